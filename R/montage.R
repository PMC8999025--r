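#' Load the default 22-channel prefrontal probe montage
#'
#' Returns the fixed prefrontal-cortex montage used throughout the package:
#' 22 source-detector channels formed by 15 optodes (7 sources, 8 detectors)
#' at 30 mm separation, with per-channel MNI coordinates, Brodmann area
#' (9/46 dorsolateral prefrontal, 10 frontopolar, 11 orbitofrontal), a
#' probabilistic registration weight, and the region-of-interest label
#' (\code{dlPFC}, \code{FPC}, \code{OFC}).
#'
#' Channel coordinates and Brodmann areas are taken as published for this
#' montage; the source/detector pairing of each channel is a nominal
#' (synthetic) interleaved assignment, since only optode counts and the
#' separation are fixed by the geometry, and no computation consumes the
#' pairing. The registration weight column is metadata only.
#'
#' @param path TSV file describing the montage; defaults to the packaged
#'   fixture.
#' @return An object of class \code{fnirs_montage}: a list with
#'   \code{channels} (data frame with columns \code{channel}, \code{source},
#'   \code{detector}, \code{brodmann}, \code{x}, \code{y}, \code{z},
#'   \code{weight}, \code{roi}), \code{optodes} (data frame \code{id},
#'   \code{role}), and \code{separation_mm}.
#' @examples
#' m <- load_default_montage()
#' m$channels[1, c("x", "y", "z")]  # MNI (34, 45, 43)
#' roi_of(m, 7)                     # "FPC"
#' @export
load_default_montage <- function(path = system.file("extdata", "montage_pfc22.tsv",
                                                    package = "rsfnirs")) {
  ch <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("channel", "brodmann", "x", "y", "z", "weight", "roi")
  if (!all(required %in% names(ch)))
    stopf("montage file %s lacks columns: %s", path,
          paste(setdiff(required, names(ch)), collapse = ", "),
          class = "rsfnirs_invalid_input")
  ch <- ch[order(ch$channel), ]
  if (!identical(ch$channel, 1:22))
    stopf("montage must define channels 1..22 exactly", class = "rsfnirs_invalid_input")
  expected_roi <- roi_partition_labels()
  if (!identical(ch$roi, unname(expected_roi)))
    stopf("montage ROI labels disagree with the fixed dlPFC/FPC/OFC partition",
          class = "rsfnirs_invalid_input")
  ba_roi <- c(`9` = "dlPFC", `46` = "dlPFC", `10` = "FPC", `11` = "OFC")
  if (!identical(unname(ba_roi[as.character(ch$brodmann)]), ch$roi))
    stopf("Brodmann areas inconsistent with ROI labels", class = "rsfnirs_invalid_input")
  if (any(ch$weight < 0 | ch$weight > 1))
    stopf("registration weights must lie in [0, 1]", class = "rsfnirs_invalid_input")

  optodes <- data.frame(
    id = c(paste0("S", 1:7), paste0("D", 1:8)),
    role = c(rep("source", 7), rep("detector", 8)),
    stringsAsFactors = FALSE
  )
  # nominal pairing: walk the channel list alternating over sources/detectors
  ch$source <- paste0("S", ((ch$channel - 1L) %% 7L) + 1L)
  ch$detector <- paste0("D", ((ch$channel - 1L) %/% 3L) %% 8L + 1L)
  ch <- ch[, c("channel", "source", "detector", "brodmann", "x", "y", "z",
               "weight", "roi")]
  structure(list(channels = ch, optodes = optodes, separation_mm = 30),
            class = "fnirs_montage")
}

# fixed ROI partition of channels 1..22
roi_partition_labels <- function() {
  roi <- rep(NA_character_, 22)
  roi[c(1:6, 8, 9, 14, 18)] <- "dlPFC"
  roi[c(7, 10:13, 15:17)] <- "FPC"
  roi[19:22] <- "OFC"
  roi
}

#' ROI membership of the default montage as a named list
#'
#' @return Named list of channel-index vectors for \code{dlPFC}, \code{FPC}
#'   and \code{OFC}; the three sets partition 1..22.
#' @export
roi_partition <- function() {
  roi <- roi_partition_labels()
  lapply(stats::setNames(nm = c("dlPFC", "FPC", "OFC")), function(r) which(roi == r))
}

#' Region of interest of a channel
#'
#' @param montage An \code{fnirs_montage}.
#' @param channel_index Channel number, 1..22 (CH01..CH22).
#' @return \code{"dlPFC"}, \code{"FPC"} or \code{"OFC"}.
#' @export
roi_of <- function(montage, channel_index) {
  n <- nrow(montage$channels)
  if (!is.numeric(channel_index) || length(channel_index) != 1L ||
      channel_index != as.integer(channel_index) ||
      channel_index < 1L || channel_index > n)
    stopf("channel index must be an integer in 1..%d", n,
          class = "rsfnirs_invalid_channel")
  montage$channels$roi[as.integer(channel_index)]
}

#' Boolean mask selecting channel pairs between (or within) two ROIs
#'
#' The mask is true for (i, j) with one endpoint in \code{roi_a} and the
#' other in \code{roi_b} (symmetric, false diagonal). Within-ROI masks
#' (\code{roi_a == roi_b}) select unordered pairs inside that ROI. Over all
#' ROI pairs the masks partition the 231 off-diagonal unordered pairs.
#'
#' @param montage An \code{fnirs_montage}.
#' @param roi_a,roi_b ROI labels.
#' @return A 22 x 22 logical matrix.
#' @export
roi_block_mask <- function(montage, roi_a, roi_b) {
  labs <- unique(montage$channels$roi)
  if (!(roi_a %in% labs) || !(roi_b %in% labs))
    stopf("unknown ROI label; expected one of %s", paste(labs, collapse = ", "),
          class = "rsfnirs_invalid_parameter")
  in_a <- montage$channels$roi == roi_a
  in_b <- montage$channels$roi == roi_b
  m <- outer(in_a, in_b, `&`) | outer(in_b, in_a, `&`)
  diag(m) <- FALSE
  dimnames(m) <- list(channel_labels(), channel_labels())
  m
}

channel_labels <- function(n = 22) sprintf("CH%02d", seq_len(n))

#' Export the montage in BrainNet-Viewer .node format
#'
#' Six whitespace-separated columns: x, y, z, ROI color code (dlPFC = 1,
#' FPC = 2, OFC = 3), node size, channel label.
#'
#' @param montage An \code{fnirs_montage}.
#' @param path Output file.
#' @param size Node sizes (length 1 or 22), e.g. degrees of a thresholded
#'   network.
#' @return \code{path}, invisibly.
#' @export
write_brainnet_node <- function(montage, path, size = 1) {
  ch <- montage$channels
  color <- match(ch$roi, c("dlPFC", "FPC", "OFC"))
  size <- rep_len(size, nrow(ch))
  lines <- sprintf("%g %g %g %d %g %s", ch$x, ch$y, ch$z, color, size,
                   channel_labels(nrow(ch)))
  writeLines(lines, path)
  invisible(path)
}
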