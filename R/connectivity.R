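#' Pearson correlation between two channel time courses
#'
#' The functional-connectivity edge weight: the sample Pearson correlation
#' of two equal-length series. Zero-variance input raises an error rather
#' than silently returning 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("series must have equal length >= 3", class = "rsfnirs_invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant series",
          class = "rsfnirs_undefined_correlation")
  stats::cor(x, y)
}

#' Channel-by-channel connectivity matrix of one recording
#'
#' @param hb An \code{hb_timeseries} (channels x samples).
#' @return A \code{connectivity_matrix}: list with \code{values}
#'   (symmetric, unit diagonal), \code{subject_id}, \code{session},
#'   \code{group_label}.
#' @export
cor_matrix <- function(hb) {
  X <- t(hb$values)
  if (nrow(X) < 3)
    stopf("need at least 3 samples", class = "rsfnirs_invalid_input")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopf("channel %s is constant; correlation undefined",
          channel_labels(ncol(X))[which(sds == 0)[1]],
          class = "rsfnirs_undefined_correlation")
  V <- stats::cor(X)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  dimnames(V) <- list(channel_labels(ncol(X)), channel_labels(ncol(X)))
  connectivity_matrix(V, subject_id = hb$subject_id, session = hb$session)
}

#' Connectivity-matrix container
#'
#' @param values Symmetric matrix with unit diagonal, off-diagonal in
#'   [-1, 1].
#' @param subject_id,session,group_label Metadata.
#' @return A \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(values, subject_id = NA_character_,
                                session = NA_character_,
                                group_label = NA_character_) {
  V <- as.matrix(values)
  if (!isSymmetric(unname(V), tol = 1e-12))
    stopf("connectivity matrix must be symmetric", class = "rsfnirs_invalid_input")
  if (any(abs(diag(V) - 1) > 1e-12))
    stopf("connectivity matrix must have unit diagonal",
          class = "rsfnirs_invalid_input")
  if (any(V < -1 - 1e-12 | V > 1 + 1e-12))
    stopf("correlations must lie in [-1, 1]", class = "rsfnirs_invalid_input")
  if (is.null(dimnames(V)))
    dimnames(V) <- list(channel_labels(nrow(V)), channel_labels(nrow(V)))
  structure(list(values = V, subject_id = subject_id, session = session,
                 group_label = group_label),
            class = "connectivity_matrix")
}

#' Element-wise group mean of connectivity matrices
#'
#' Plain arithmetic average (no Fisher z by default; set
#' \code{fisher_z = TRUE} to average in z-space and back-transform).
#'
#' @param mats Non-empty list of \code{connectivity_matrix} objects of the
#'   same dimension.
#' @param fisher_z Average atanh-transformed values instead.
#' @param group_label Label attached to the mean matrix.
#' @return A \code{connectivity_matrix}.
#' @export
group_mean_cor <- function(mats, fisher_z = FALSE, group_label = NA_character_) {
  if (length(mats) == 0)
    stopf("empty list of matrices", class = "rsfnirs_invalid_input")
  vals <- lapply(mats, function(m) m$values)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1))))
    stopf("matrices differ in shape", class = "rsfnirs_invalid_input")
  if (fisher_z) {
    z <- Reduce(`+`, lapply(vals, function(v) atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)))) /
      length(vals)
    M <- tanh(z)
  } else {
    M <- Reduce(`+`, vals) / length(vals)
  }
  diag(M) <- 1
  connectivity_matrix(M, session = mats[[1]]$session, group_label = group_label)
}

#' Mean connectivity of a matrix
#'
#' Mean of the 231 (for 22 channels) strict upper-triangle entries, signed.
#'
#' @param mat A \code{connectivity_matrix}.
#' @return Scalar mean correlation.
#' @export
mean_cor_scalar <- function(mat) {
  V <- mat$values
  mean(V[upper.tri(V)])
}

#' Binarize a connectivity matrix at an absolute correlation threshold
#'
#' Edge (i, j) present iff \eqn{r_{ij} > } \code{threshold} (strict), i != j.
#' Negative correlations are retained upstream but can never pass a
#' positive threshold.
#'
#' @param mat A \code{connectivity_matrix}.
#' @param threshold Correlation cut in (-1, 1); default 0.7.
#' @return A \code{binary_network}: list with \code{adjacency} (0/1,
#'   zero diagonal), \code{threshold_used}, \code{thresholding_mode}.
#' @export
binarize <- function(mat, threshold = 0.7) {
  assert_scalar_number(threshold, "threshold", lower = -1, upper = 1)
  if (threshold <= -1 || threshold >= 1)
    stopf("threshold must lie strictly inside (-1, 1)",
          class = "rsfnirs_invalid_parameter")
  A <- (mat$values > threshold) * 1L
  diag(A) <- 0L
  binary_network(A, threshold_used = threshold, thresholding_mode = "absolute_r")
}

#' Binary-network container
#'
#' @param adjacency Symmetric 0/1 matrix, zero diagonal.
#' @param threshold_used,thresholding_mode Provenance of the thresholding.
#' @return A \code{binary_network}.
#' @export
binary_network <- function(adjacency, threshold_used = NA_real_,
                           thresholding_mode = c("absolute_r", "density")) {
  A <- as.matrix(adjacency)
  mode(A) <- "integer"
  if (!isSymmetric(unname(A)))
    stopf("adjacency must be symmetric", class = "rsfnirs_invalid_input")
  if (any(diag(A) != 0L))
    stopf("self-loops are not allowed", class = "rsfnirs_invalid_input")
  if (!all(A %in% c(0L, 1L)))
    stopf("adjacency must be 0/1", class = "rsfnirs_invalid_input")
  dimnames(A) <- list(channel_labels(nrow(A)), channel_labels(nrow(A)))
  structure(list(adjacency = A, threshold_used = threshold_used,
                 thresholding_mode = match.arg(thresholding_mode)),
            class = "binary_network")
}
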