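#' Percentage of a count, print-rounded
#'
#' \code{100 * count / total}, rounded half away from zero to one decimal
#' (the convention of printed demographic tables).
#'
#' @param count Non-negative integer, \code{count <= total}.
#' @param total Positive integer.
#' @return Percentage with one decimal.
#' @export
percentage <- function(count, total) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stopf("total must be a positive number", class = "rsfnirs_invalid_input")
  if (!is.numeric(count) || any(count < 0) || any(count > total))
    stopf("count must satisfy 0 <= count <= total", class = "rsfnirs_invalid_input")
  round_half_up(100 * count / total, 1)
}

#' Load the packaged demographic counts of the three-shift cohort
#'
#' Marital-status and education counts for the 54-worker cohort and its
#' three shift groups (morning n = 17, afternoon n = 18, night n = 19).
#'
#' @param path TSV with columns \code{section}, \code{category},
#'   \code{total}, \code{group1}, \code{group2}, \code{group3}.
#' @return A \code{demographic_table} data frame.
#' @export
load_default_demographics <- function(path = system.file(
  "extdata", "demographics_54workers.tsv", package = "rsfnirs")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(tab, class = c("demographic_table", "data.frame"))
}

#' Per-category demographic percentages, overall and per group
#'
#' Applies [percentage()] to every cell; validates that group counts sum
#' to the overall count in every row.
#'
#' @param table A \code{demographic_table} (see
#'   [load_default_demographics()]).
#' @param group_sizes Named totals per group column; default the
#'   17/18/19 shift groups.
#' @return Data frame with the original counts plus \code{pct_total},
#'   \code{pct_group1}, \code{pct_group2}, \code{pct_group3}.
#' @export
demographic_summary <- function(table,
                                group_sizes = c(group1 = 17, group2 = 18,
                                                group3 = 19)) {
  groups <- names(group_sizes)
  bad <- which(rowSums(table[, groups, drop = FALSE]) != table$total)
  if (length(bad))
    stopf("group counts do not sum to the overall count in row %d (%s)",
          bad[1], table$category[bad[1]], class = "rsfnirs_inconsistency")
  if (any(table$total < 0))
    stopf("counts must be non-negative", class = "rsfnirs_invalid_input")
  n_total <- sum(group_sizes)
  out <- table
  out$pct_total <- percentage(table$total, n_total)
  for (g in groups)
    out[[paste0("pct_", g)]] <- percentage(table[[g]], group_sizes[[g]])
  out
}
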