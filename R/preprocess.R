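#' Default hemoglobin extinction-coefficient table
#'
#' 2 x 2 matrix of molar extinction coefficients in 1/(mM cm); rows are
#' wavelengths (690, 830 nm), columns the chromophores (HbO, HbR). Values
#' from the standard published compendium; editable by passing a different
#' TSV path.
#'
#' @param path TSV with columns \code{wavelength_nm}, \code{hbo},
#'   \code{hbr}.
#' @return Numeric matrix with wavelength rownames.
#' @export
default_extinction <- function(path = system.file("extdata", "extinction_690_830.tsv",
                                                  package = "rsfnirs")) {
  tab <- utils::read.delim(path, comment.char = "#")
  m <- as.matrix(tab[, c("hbo", "hbr")])
  rownames(m) <- tab$wavelength_nm
  colnames(m) <- c("hbo", "hbr")
  m
}

#' Parameters of the modified Beer-Lambert inversion
#'
#' @param dpf Differential pathlength factor; the single mean value 6.53 is
#'   used for both wavelengths by default (wavelength-specific DPFs may be
#'   given as a length-2 vector).
#' @param separation_mm Source-detector separation (mm), converted to cm
#'   internally.
#' @param extinction 2 x 2 extinction matrix, see [default_extinction()].
#' @return An \code{mbll_params} list.
#' @export
mbll_params <- function(dpf = 6.53, separation_mm = 30,
                        extinction = default_extinction()) {
  if (any(dpf <= 0)) stopf("dpf must be positive", class = "rsfnirs_invalid_parameter")
  ext <- as.matrix(extinction)
  if (!all(dim(ext) == c(2, 2)) || kappa(ext) > 1e6)
    stopf("extinction matrix must be 2x2 and well conditioned",
          class = "rsfnirs_configuration_error")
  structure(list(dpf = rep_len(dpf, 2), separation_mm = separation_mm,
                 extinction = ext),
            class = "mbll_params")
}

#' Optical-density changes from raw intensities
#'
#' Per channel and wavelength, \eqn{\Delta OD(t) = -\log_{10}(I(t)/\bar I)}.
#' The reference \eqn{\bar I} is the temporal mean of the trace (the
#' continuous-wave convention: only intensity changes are meaningful), or,
#' for recordings that carry their true resting baseline (synthetic data),
#' that baseline — which makes the Beer-Lambert round trip exact rather
#' than exact-up-to-a-constant. The constant is immaterial downstream:
#' the band-pass removes it and correlation is offset-invariant.
#'
#' @param rec A \code{raw_intensity} object (strictly positive intensities).
#' @param reference \code{"temporal_mean"} (default) or \code{"baseline"}.
#' @return channels x wavelengths x samples array of OD changes.
#' @export
intensity_to_od <- function(rec, reference = c("temporal_mean", "baseline")) {
  reference <- match.arg(reference)
  inten <- rec$intensities
  bad <- which(!(is.finite(inten) & inten > 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-positive intensity at channel %d, wavelength index %d, sample %d",
          bad[1, 1], bad[1, 2], bad[1, 3], class = "rsfnirs_invalid_input")
  if (reference == "baseline" && is.null(rec$baseline))
    stopf("recording carries no baseline; use reference = \"temporal_mean\"",
          class = "rsfnirs_invalid_input")
  od <- inten
  for (w in seq_len(dim(inten)[2])) {
    x <- inten[, w, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = dim(inten)[1])
    ref <- if (reference == "baseline") rec$baseline[, w] else rowMeans(x)
    od[, w, ] <- -log10(x / ref)
  }
  od
}

#' Zero-phase hemodynamic band-pass filter
#'
#' Realized as a cascade of 4th-order Butterworth high-pass (at
#' \code{low_hz}) and low-pass (at \code{high_hz}) sections, each applied
#' forward-backward (\code{signal::filtfilt}) for zero phase. The cascade
#' form keeps the recursion numerically well conditioned at the very low
#' normalized corner frequencies of fNIRS sampling rates.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate (Hz); must exceed \code{2 * high_hz}.
#' @param low_hz,high_hz Passband edges, default 0.02-0.1 Hz.
#' @param order Butterworth order of each section.
#' @return Filtered series, same length.
#' @export
bandpass <- function(x, fs, low_hz = 0.02, high_hz = 0.1, order = 4) {
  if (!is.numeric(x) || length(x) < 3 * 2 * order)
    stopf("series too short for the filter order", class = "rsfnirs_invalid_input")
  if (fs <= 2 * high_hz)
    stopf("sampling rate must exceed twice the upper band edge",
          class = "rsfnirs_invalid_parameter")
  if (!(low_hz > 0 && low_hz < high_hz))
    stopf("need 0 < low_hz < high_hz", class = "rsfnirs_invalid_parameter")
  nyq <- fs / 2
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
}

#' Modified Beer-Lambert inversion of optical-density changes
#'
#' Per channel and sample, solves the 2 x 2 linear system
#' \eqn{\Delta OD_\lambda = (\epsilon_{HbO,\lambda} \Delta HbO +
#' \epsilon_{HbR,\lambda} \Delta HbR)\, d\, DPF_\lambda} for
#' \eqn{(\Delta HbO, \Delta HbR)}, with \eqn{d} the separation in cm.
#'
#' @param od channels x wavelengths x samples OD array (both wavelengths).
#' @param params An \code{mbll_params}.
#' @param fs_hz,subject_id,session Metadata for the resulting series.
#' @return List with \code{oxy} and \code{deoxy} \code{hb_timeseries} (mM).
#' @export
mbll <- function(od, params = mbll_params(), fs_hz = 7.4074,
                 subject_id = "subj", session = "pre") {
  if (length(dim(od)) != 3 || dim(od)[2] != 2)
    stopf("od must be channels x 2 wavelengths x samples",
          class = "rsfnirs_invalid_input")
  A <- params$extinction * (params$separation_mm / 10) * params$dpf
  Ainv <- solve(A)
  n_ch <- dim(od)[1]; n_t <- dim(od)[3]
  od1 <- matrix(od[, 1, ], n_ch, n_t)
  od2 <- matrix(od[, 2, ], n_ch, n_t)
  oxy <- Ainv[1, 1] * od1 + Ainv[1, 2] * od2
  deoxy <- Ainv[2, 1] * od1 + Ainv[2, 2] * od2
  list(oxy = hb_timeseries(oxy, fs_hz, "oxy", subject_id, session),
       deoxy = hb_timeseries(deoxy, fs_hz, "deoxy", subject_id, session))
}

#' Full preprocessing of one raw recording
#'
#' Applies, per channel: optical-density conversion, the 0.02-0.1 Hz
#' zero-phase band-pass, wavelet despiking (both on OD, where the stages
#' commute with the linear Beer-Lambert inversion), then the MBLL 2 x 2
#' solve. Returns the oxy-Hb series; deoxy is attached as attribute
#' \code{"deoxy"}.
#'
#' @param rec A \code{raw_intensity}.
#' @param wavelet A \code{wavelet_params}.
#' @param mbll_p An \code{mbll_params}.
#' @param low_hz,high_hz Band edges (Hz).
#' @return An \code{hb_timeseries} (oxy) with attribute \code{deoxy}.
#' @export
preprocess_subject <- function(rec, wavelet = wavelet_params(),
                               mbll_p = mbll_params(),
                               low_hz = 0.02, high_hz = 0.1) {
  od <- intensity_to_od(rec)
  for (ch in seq_len(dim(od)[1])) {
    for (w in 1:2) {
      x <- bandpass(od[ch, w, ], fs = rec$fs_hz, low_hz = low_hz, high_hz = high_hz)
      od[ch, w, ] <- wavelet_despike(x, wavelet)
    }
  }
  hb <- mbll(od, mbll_p, fs_hz = rec$fs_hz, subject_id = rec$subject_id,
             session = rec$session)
  out <- hb$oxy
  attr(out, "deoxy") <- hb$deoxy
  out
}
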