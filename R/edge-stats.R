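#' Paired t-test on two matched samples
#'
#' Two-sided Student t on the within-subject differences
#' \code{pre - post}. If the differences have zero variance the test is
#' degenerate: all-zero differences give \code{t = 0, p = 1} (no evidence
#' of change); a constant non-zero shift is flagged degenerate and carries
#' no p-value, and such edges are excluded from the multiplicity count of
#' downstream FDR correction.
#'
#' @param pre,post Numeric vectors of equal length n >= 2.
#' @return List with \code{t}, \code{p}, \code{df}, \code{degenerate}.
#' @export
paired_t <- function(pre, post) {
  n <- length(pre)
  if (length(post) != n || n < 2)
    stopf("paired samples must have equal length >= 2",
          class = "rsfnirs_invalid_input")
  d <- pre - post
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = n - 1, degenerate = TRUE))
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up procedure at level \code{q}: with p-values sorted ascending,
#' find the largest rank k with \eqn{p_{(k)} \le k q / m} and reject all
#' ranks up to k. \code{NA} p-values (degenerate tests) are excluded from
#' m and never rejected.
#'
#' @param pvals Numeric p-values in [0, 1] (NAs allowed).
#' @param q FDR level, default 0.05.
#' @return Logical vector, TRUE where rejected.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  assert_scalar_number(q, "q", lower = 0, upper = 1)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stopf("p-values must lie in [0, 1]", class = "rsfnirs_invalid_input")
  rej <- rep(FALSE, length(pvals))
  if (any(ok))
    rej[ok] <- stats::p.adjust(pvals[ok], method = "BH") <= q
  rej
}

#' Paired edge samples of a cohort
#'
#' Stacks per-subject connectivity values over the strict upper triangle
#' (row-major edge order (1,2), (1,3), ..., (21,22)) for the pre and post
#' sessions.
#'
#' @param pre_mats,post_mats Equal-length lists of
#'   \code{connectivity_matrix} objects, one per subject, matched by
#'   position.
#' @param group_label Optional label.
#' @return A \code{paired_edge_samples}: list with \code{pre}, \code{post}
#'   (subjects x edges matrices) and \code{edge_index} (i < j).
#' @export
paired_edge_samples <- function(pre_mats, post_mats, group_label = NA_character_) {
  if (length(pre_mats) != length(post_mats) || length(pre_mats) < 2)
    stopf("paired design needs matching pre/post lists of >= 2 subjects",
          class = "rsfnirs_invalid_input")
  n_ch <- nrow(pre_mats[[1]]$values)
  pairs <- upper_tri_pairs(n_ch)
  pull <- function(m) m$values[cbind(pairs[, 1], pairs[, 2])]
  pre <- do.call(rbind, lapply(pre_mats, pull))
  post <- do.call(rbind, lapply(post_mats, pull))
  colnames(pre) <- colnames(post) <-
    paste0(channel_labels(n_ch)[pairs[, 1]], "-", channel_labels(n_ch)[pairs[, 2]])
  structure(list(pre = pre, post = post, edge_index = pairs,
                 group_label = group_label),
            class = "paired_edge_samples")
}

#' Edge-wise paired t-tests with FDR correction
#'
#' Runs [paired_t()] on every edge (vectorized) and applies
#' Benjamini-Hochberg FDR across the non-degenerate edges.
#'
#' @param samples A \code{paired_edge_samples}.
#' @param q FDR level, default 0.05.
#' @param alpha Raw per-edge significance level reported alongside.
#' @return An \code{edge_test_result}: data frame with columns \code{edge},
#'   \code{i}, \code{j}, \code{t}, \code{p}, \code{p_significant},
#'   \code{q_significant}, \code{degenerate}; attributes \code{q},
#'   \code{alpha}, \code{n}.
#' @export
edgewise_paired_test <- function(samples, q = 0.05, alpha = 0.05) {
  D <- samples$pre - samples$post
  n <- nrow(D)
  if (n < 2) stopf("need >= 2 subjects", class = "rsfnirs_invalid_input")
  m <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, NA_real_))
  p <- ifelse(is.na(t_stat), NA_real_,
              ifelse(s > 0 | m == 0, 2 * stats::pt(-abs(t_stat), df = n - 1), NA_real_))
  p[t_stat == 0 & s == 0] <- 1  # all-zero differences
  degenerate <- is.na(p)
  res <- data.frame(
    edge = colnames(samples$pre),
    i = samples$edge_index[, 1], j = samples$edge_index[, 2],
    t = t_stat, p = p,
    p_significant = !is.na(p) & p < alpha,
    q_significant = fdr_bh(p, q),
    degenerate = degenerate,
    row.names = NULL
  )
  structure(res, class = c("edge_test_result", "data.frame"),
            q = q, alpha = alpha, n = n)
}

#' Paired comparison of per-subject mean connectivity
#'
#' The whole-matrix summary test: [mean_cor_scalar()] per subject and
#' session, then a paired t-test of the pre vs post scalars.
#'
#' @param pre_mats,post_mats Lists of per-subject
#'   \code{connectivity_matrix} objects (matched by position), or numeric
#'   vectors of precomputed mean-correlation scalars.
#' @return As [paired_t()], plus \code{mean_pre} and \code{mean_post}.
#' @export
mean_cor_paired_test <- function(pre_mats, post_mats) {
  to_scalar <- function(x)
    if (is.numeric(x)) x else vapply(x, mean_cor_scalar, numeric(1))
  pre <- to_scalar(pre_mats)
  post <- to_scalar(post_mats)
  out <- paired_t(pre, post)
  out$mean_pre <- mean(pre)
  out$mean_post <- mean(post)
  out
}
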