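# TSV readers/writers for the package's tabular interchange formats and
# BrainNet-Viewer-compatible exports.

#' Write an Hb time series as a channel x time TSV
#'
#' First column \code{channel} (CH01..), remaining columns samples; a
#' header comment records sampling rate, chromophore and session.
#'
#' @param hb An \code{hb_timeseries}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_hb_tsv <- function(hb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g chromophore=%s subject=%s session=%s",
                     hb$fs_hz, hb$chromophore, hb$subject_id, hb$session), con)
  df <- data.frame(channel = rownames(hb$values),
                   format(hb$values, digits = 17, trim = TRUE, scientific = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an Hb time series written by [write_hb_tsv()]
#'
#' @param path TSV file.
#' @return An \code{hb_timeseries}.
#' @export
read_hb_tsv <- function(path) {
  if (!file.exists(path))
    stopf("input file does not exist: %s", path, class = "rsfnirs_data_error")
  header <- readLines(path, n = 1)
  meta <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  colnames(m) <- NULL
  hb_timeseries(m, fs_hz = as.numeric(vals[["fs_hz"]]),
                chromophore = vals[["chromophore"]],
                subject_id = vals[["subject"]], session = vals[["session"]])
}

#' Write a connectivity matrix as labeled TSV
#' @param mat A \code{connectivity_matrix}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_cor_tsv <- function(mat, path) {
  df <- data.frame(channel = rownames(mat$values),
                   format(mat$values, digits = 17, trim = TRUE))
  names(df) <- c("channel", colnames(mat$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_cor_tsv()]
#' @param path TSV file.
#' @return A \code{connectivity_matrix}.
#' @export
read_cor_tsv <- function(path) {
  if (!file.exists(path))
    stopf("input file does not exist: %s", path, class = "rsfnirs_data_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  colnames(m) <- tab[[1]]
  m <- (m + t(m)) / 2  # absorb decimal round-trip asymmetry
  diag(m) <- 1
  connectivity_matrix(m)
}

#' Export a binary network in BrainNet-Viewer .edge format
#'
#' Whitespace-separated n x n adjacency matrix.
#'
#' @param net A \code{binary_network}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_brainnet_edge <- function(net, path) {
  utils::write.table(net$adjacency, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write edge-wise test results as a TSV sorted by p-value
#'
#' Columns: edge (CHxx-CHyy), roi_pair, t, p, fdr_significant.
#'
#' @param result An \code{edge_test_result}.
#' @param path Output file.
#' @param montage Montage used to label ROI pairs.
#' @return \code{path}, invisibly.
#' @export
write_edge_test_tsv <- function(result, path, montage = load_default_montage()) {
  roi <- montage$channels$roi
  roi_pair <- paste0(roi[result$i], "-", roi[result$j])
  df <- data.frame(edge = result$edge, roi_pair = roi_pair,
                   t = result$t, p = result$p,
                   fdr_significant = result$q_significant)
  df <- df[order(df$p), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
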