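#' Nuisance-noise specification for synthetic recordings
#'
#' Physiological and instrumental nuisance components added on top of the
#' band-limited hemodynamic signal: cardiac, respiratory and Mayer-wave
#' oscillations (independent random phase per channel), a random linear
#' drift, white measurement noise, and sparse motion spikes (boxcar onset
#' with exponential recovery). Amplitudes are in the same concentration
#' units as the hemodynamic signal (mM); the defaults are sized relative to
#' the 1e-3 mM hemodynamic scale used by [simulate_hb()].
#'
#' @param cardiac_hz,resp_hz,mayer_hz Oscillator frequencies (Hz); must lie
#'   below the Nyquist frequency of the recording they are used with.
#' @param osc_amplitudes Named numeric vector of oscillator amplitudes (mM)
#'   for \code{cardiac}, \code{resp}, \code{mayer}.
#' @param drift_slope_sd SD of the per-channel linear drift slope, mM per
#'   minute.
#' @param white_sd SD of white noise per sample (mM).
#' @param spike_rate_per_min Expected motion-spike count per minute per
#'   channel.
#' @param spike_amplitude_sd SD of spike amplitudes (mM).
#' @return A \code{noise_spec} list.
#' @export
noise_spec <- function(cardiac_hz = 1.2, resp_hz = 0.3, mayer_hz = 0.1,
                       osc_amplitudes = c(cardiac = 2e-4, resp = 1.5e-4, mayer = 3e-4),
                       drift_slope_sd = 2e-4, white_sd = 1e-4,
                       spike_rate_per_min = 1, spike_amplitude_sd = 2e-3) {
  amps <- osc_amplitudes[c("cardiac", "resp", "mayer")]
  if (any(is.na(amps)) || any(amps < 0))
    stopf("osc_amplitudes must be named (cardiac, resp, mayer) and non-negative",
          class = "rsfnirs_invalid_parameter")
  for (nm in c("drift_slope_sd", "white_sd", "spike_rate_per_min", "spike_amplitude_sd"))
    assert_scalar_number(get(nm), nm, lower = 0)
  for (nm in c("cardiac_hz", "resp_hz", "mayer_hz"))
    assert_scalar_number(get(nm), nm, lower = 0)
  structure(list(cardiac_hz = cardiac_hz, resp_hz = resp_hz, mayer_hz = mayer_hz,
                 osc_amplitudes = amps, drift_slope_sd = drift_slope_sd,
                 white_sd = white_sd, spike_rate_per_min = spike_rate_per_min,
                 spike_amplitude_sd = spike_amplitude_sd),
            class = "noise_spec")
}

#' Noise specification with every nuisance component switched off
#' @return A \code{noise_spec} with all amplitudes and rates zero.
#' @export
noise_spec_silent <- function() {
  noise_spec(osc_amplitudes = c(cardiac = 0, resp = 0, mayer = 0),
             drift_slope_sd = 0, white_sd = 0,
             spike_rate_per_min = 0, spike_amplitude_sd = 0)
}

#' ROI-block ground-truth correlation structure
#'
#' Builds the population channel-by-channel correlation matrix used as
#' ground truth by the simulator: \code{within_r} on off-diagonal entries
#' inside each ROI block, \code{between_r} across blocks, unit diagonal.
#' If the block matrix is not positive semi-definite it is repaired by
#' clipping negative eigenvalues at zero and renormalizing the diagonal.
#'
#' @param partition Named list of channel-index vectors (default the
#'   dlPFC/FPC/OFC partition of the packaged montage).
#' @param within_r,between_r Correlations; require
#'   \code{-1 < between_r <= within_r < 1}.
#' @param hemo_band Passband (Hz) of the hemodynamic process the matrix
#'   parameterizes.
#' @return A \code{ground_truth} list with elements \code{correlation}
#'   (22 x 22) and \code{hemo_band}.
#' @export
make_block_correlation <- function(partition = roi_partition(), within_r,
                                   between_r, hemo_band = c(0.02, 0.1)) {
  assert_scalar_number(within_r, "within_r", lower = -1, upper = 1)
  assert_scalar_number(between_r, "between_r", lower = -1, upper = 1)
  if (!(between_r > -1 && between_r <= within_r && within_r < 1))
    stopf("require -1 < between_r <= within_r < 1",
          class = "rsfnirs_invalid_parameter")
  idx <- unlist(partition)
  n <- length(idx)
  if (!setequal(idx, seq_len(n)))
    stopf("partition must cover channels 1..n exactly once",
          class = "rsfnirs_invalid_parameter")
  C <- matrix(between_r, n, n)
  for (blk in partition) C[blk, blk] <- within_r
  diag(C) <- 1
  ground_truth(C, hemo_band)
}

#' Construct a ground-truth object from an explicit correlation matrix
#'
#' @param correlation Symmetric matrix with unit diagonal; repaired to the
#'   nearest valid correlation matrix by eigenvalue clipping if needed.
#' @param hemo_band Passband (Hz).
#' @return A \code{ground_truth} list.
#' @export
ground_truth <- function(correlation, hemo_band = c(0.02, 0.1)) {
  C <- as.matrix(correlation)
  if (!isSymmetric(C, tol = 1e-10))
    stopf("correlation matrix must be symmetric", class = "rsfnirs_invalid_parameter")
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    v <- pmax(ev$values, 0)
    C <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(C))
    C <- C / outer(d, d)
    C <- (C + t(C)) / 2
  }
  diag(C) <- 1
  dimnames(C) <- list(channel_labels(nrow(C)), channel_labels(nrow(C)))
  structure(list(correlation = C, hemo_band = as.numeric(hemo_band)),
            class = "ground_truth")
}

#' Oxy-Hb time-series container
#'
#' @param values channels x samples matrix of concentration changes (mM).
#' @param fs_hz Sampling rate (Hz).
#' @param chromophore \code{"oxy"} or \code{"deoxy"}.
#' @param subject_id,session Identifiers (\code{session} is \code{"pre"} or
#'   \code{"post"}).
#' @return An \code{hb_timeseries} object.
#' @export
hb_timeseries <- function(values, fs_hz, chromophore = "oxy",
                          subject_id = "subj", session = "pre") {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stopf("Hb values must be finite", class = "rsfnirs_invalid_input")
  assert_scalar_number(fs_hz, "fs_hz", lower = 1e-9)
  chromophore <- match.arg(chromophore, c("oxy", "deoxy"))
  session <- match.arg(session, c("pre", "post"))
  rownames(values) <- channel_labels(nrow(values))
  structure(list(values = values, fs_hz = fs_hz, chromophore = chromophore,
                 subject_id = subject_id, session = session),
            class = "hb_timeseries")
}

#' Simulate a resting-state oxy-Hb recording with planted connectivity
#'
#' Generates a channels x samples concentration-change matrix whose
#' hemodynamic component is a band-limited Gaussian process (white noise
#' passed through the same 0.02-0.1 Hz zero-phase Butterworth cascade used
#' in preprocessing) with cross-channel correlation imposed by the
#' symmetric square root of the ground-truth matrix, so the planted
#' quantity is exactly the population Pearson correlation of the process.
#' Independent nuisance oscillators, linear drift, white noise and motion
#' spikes (per \code{noise}) are then added. Deterministic given
#' \code{seed}.
#'
#' @param truth A \code{ground_truth}.
#' @param duration_s Recording length in seconds (default 300).
#' @param fs Sampling rate in Hz (default 7.4074).
#' @param noise A \code{noise_spec}.
#' @param seed Integer seed.
#' @param hemo_sd SD of the hemodynamic component per channel (mM).
#' @param subject_id,session Identifiers carried into the result.
#' @return An \code{hb_timeseries} (chromophore \code{"oxy"}).
#' @export
simulate_hb <- function(truth, duration_s = 300, fs = 7.4074,
                        noise = noise_spec(), seed, hemo_sd = 1e-3,
                        subject_id = "subj", session = "pre") {
  n_samp <- floor(duration_s * fs)
  if (!is.finite(n_samp) || n_samp < 64)
    stopf("duration_s * fs must give at least 64 samples",
          class = "rsfnirs_invalid_parameter")
  nyq <- fs / 2
  if (max(noise$cardiac_hz, noise$resp_hz, noise$mayer_hz) >= nyq &&
      any(noise$osc_amplitudes > 0))
    stopf("nuisance oscillator frequencies must lie below Nyquist (%g Hz)", nyq,
          class = "rsfnirs_invalid_parameter")
  C <- truth$correlation
  n_ch <- nrow(C)
  ev <- eigen(C, symmetric = TRUE)
  Rhalf <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))

  with_seed(seed, {
    W <- matrix(stats::rnorm(n_samp * n_ch), n_samp, n_ch)
    B <- apply(W, 2, bandpass, fs = fs,
               low_hz = truth$hemo_band[1], high_hz = truth$hemo_band[2])
    sds <- apply(B, 2, stats::sd)
    B <- sweep(B, 2, sds, "/")
    X <- hemo_sd * (B %*% Rhalf)                     # samples x channels

    tt <- (seq_len(n_samp) - 1) / fs
    for (ch in seq_len(n_ch)) {
      for (comp in c("cardiac", "resp", "mayer")) {
        a <- noise$osc_amplitudes[[comp]]
        if (a > 0) {
          f <- switch(comp, cardiac = noise$cardiac_hz, resp = noise$resp_hz,
                      mayer = noise$mayer_hz)
          X[, ch] <- X[, ch] + a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
        }
      }
      if (noise$drift_slope_sd > 0)
        X[, ch] <- X[, ch] + stats::rnorm(1, 0, noise$drift_slope_sd) * tt / 60
      if (noise$white_sd > 0)
        X[, ch] <- X[, ch] + stats::rnorm(n_samp, 0, noise$white_sd)
      if (noise$spike_rate_per_min > 0 && noise$spike_amplitude_sd > 0) {
        n_spk <- stats::rpois(1, noise$spike_rate_per_min * duration_s / 60)
        if (n_spk > 0)
          X[, ch] <- X[, ch] +
            spike_train(n_samp, fs, n_spk, noise$spike_amplitude_sd)
      }
    }
    hb_timeseries(t(X), fs_hz = fs, chromophore = "oxy",
                  subject_id = subject_id, session = session)
  })
}

# boxcar onset (~0.5 s) with exponential recovery (~2 s time constant)
spike_train <- function(n_samp, fs, n_spk, amp_sd) {
  out <- numeric(n_samp)
  onsets <- sample.int(n_samp, n_spk, replace = TRUE)
  box <- max(1L, round(0.5 * fs))
  tau <- 2 * fs
  decay_len <- min(n_samp, ceiling(6 * tau))
  for (s in seq_len(n_spk)) {
    a <- stats::rnorm(1, 0, amp_sd)
    t0 <- onsets[s]
    idx <- t0:min(n_samp, t0 + box - 1L)
    out[idx] <- out[idx] + a
    rec <- (t0 + box):min(n_samp, t0 + box + decay_len)
    if (rec[1] <= n_samp)
      out[rec] <- out[rec] + a * exp(-(seq_along(rec) - 1) / tau)
  }
  out
}

#' Convert Hb concentration changes to dual-wavelength intensities
#'
#' Exact inverse of the modified Beer-Lambert law used by [mbll()]:
#' per channel and wavelength, \eqn{\Delta OD = (\epsilon_{HbO}\Delta HbO +
#' \epsilon_{HbR}\Delta HbR)\, d\, DPF} and \eqn{I(t) = I_0\,10^{-\Delta OD}}.
#' If only oxy-Hb is supplied, deoxy is taken as zero (flagged in the
#' result).
#'
#' @param hb An \code{hb_timeseries} (oxy), or list
#'   \code{list(oxy =, deoxy =)}.
#' @param baseline_intensity Positive baseline intensity; scalar, or a
#'   channels x 2 matrix (columns = wavelengths).
#' @param dpf Differential pathlength factor (default 6.53).
#' @param separation_mm Source-detector separation (default 30).
#' @param extinction 2 x 2 extinction matrix (rows = wavelengths 690/830 nm,
#'   columns = HbO/HbR), 1/(mM cm); default the packaged table.
#' @return A \code{raw_intensity} object with a \code{deoxy_assumed_zero}
#'   flag.
#' @export
hb_to_intensity <- function(hb, baseline_intensity = 1, dpf = 6.53,
                            separation_mm = 30,
                            extinction = default_extinction()) {
  if (inherits(hb, "hb_timeseries")) {
    oxy <- hb
    deoxy_vals <- matrix(0, nrow(hb$values), ncol(hb$values))
    assumed <- TRUE
  } else {
    oxy <- hb$oxy
    deoxy_vals <- hb$deoxy$values
    assumed <- FALSE
  }
  if (any(baseline_intensity <= 0))
    stopf("baseline intensity must be positive", class = "rsfnirs_invalid_parameter")
  assert_scalar_number(dpf, "dpf", lower = 1e-9)
  n_ch <- nrow(oxy$values); n_t <- ncol(oxy$values)
  d_cm <- separation_mm / 10
  base <- if (length(baseline_intensity) == 1L)
    matrix(baseline_intensity, n_ch, 2) else as.matrix(baseline_intensity)

  inten <- array(NA_real_, dim = c(n_ch, 2, n_t),
                 dimnames = list(channel_labels(n_ch),
                                 paste0("wl", rownames(extinction)), NULL))
  for (w in 1:2) {
    od <- (extinction[w, 1] * oxy$values + extinction[w, 2] * deoxy_vals) *
      d_cm * dpf
    inten[, w, ] <- base[, w] * 10^(-od)
  }
  structure(list(intensities = inten, baseline = base,
                 wavelengths_nm = as.numeric(rownames(extinction)),
                 fs_hz = oxy$fs_hz, subject_id = oxy$subject_id,
                 session = oxy$session, deoxy_assumed_zero = assumed),
            class = "raw_intensity")
}

#' Generate a paired pre/post synthetic cohort
#'
#' Every subject receives an independent pre and post recording drawn from
#' \code{truth_pre} and \code{truth_post}; per-subject, per-session seeds
#' are derived deterministically from \code{seed}, so the whole cohort is a
#' pure function of its arguments.
#'
#' @param n_subjects Number of subjects (>= 2); the study groups default to
#'   17/18/19 for morning/afternoon/night shifts.
#' @param truth_pre,truth_post \code{ground_truth} objects.
#' @param duration_s,fs,noise,hemo_sd Passed to [simulate_hb()].
#' @param seed Master seed.
#' @param group_label \code{"morning"}, \code{"afternoon"} or
#'   \code{"night"}.
#' @param as_intensity If \code{TRUE}, each recording is pushed through the
#'   forward optical model ([hb_to_intensity()]) so the cohort exercises the
#'   full preprocessing chain.
#' @return A \code{synthetic_cohort}: list with \code{subjects} (each a
#'   list with \code{pre}, \code{post}), \code{truth_pre}, \code{truth_post},
#'   \code{group_label}, \code{seed}, \code{fs}, \code{duration_s}.
#' @export
generate_paired_cohort <- function(n_subjects, truth_pre, truth_post,
                                   duration_s = 300, fs = 7.4074,
                                   noise = noise_spec(), seed,
                                   group_label = "morning",
                                   as_intensity = FALSE, hemo_sd = 1e-3) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stopf("n_subjects must be >= 2", class = "rsfnirs_invalid_parameter")
  group_label <- match.arg(group_label, c("morning", "afternoon", "night"))
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("%s%02d", substr(group_label, 1, 1), i)
    rec <- lapply(c(pre = 1L, post = 2L), function(sess) {
      truth <- if (sess == 1L) truth_pre else truth_post
      hb <- simulate_hb(truth, duration_s = duration_s, fs = fs, noise = noise,
                        seed = derive_seed(seed, i, sess), hemo_sd = hemo_sd,
                        subject_id = id,
                        session = c("pre", "post")[sess])
      if (as_intensity) hb_to_intensity(hb) else hb
    })
    subjects[[i]] <- rec
  }
  structure(list(subjects = subjects, truth_pre = truth_pre,
                 truth_post = truth_post, group_label = group_label,
                 seed = seed, fs = fs, duration_s = duration_s),
            class = "synthetic_cohort")
}
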