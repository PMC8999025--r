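fs <- 7.4074

test_that("optical-density conversion matches the direct formula", {
  gt <- block_truth(0.6)
  hb <- simulate_hb(gt, duration_s = 60, seed = 7)
  ri <- hb_to_intensity(hb, baseline_intensity = 3)
  od <- intensity_to_od(ri)

  # independent recomputation per trace
  for (ch in c(1, 10, 22)) for (w in 1:2) {
    x <- ri$intensities[ch, w, ]
    expect_equal(od[ch, w, ], -log10(x / mean(x)), tolerance = 1e-12)
    expect_equal(mean(10^(-od[ch, w, ])), 1, tolerance = 1e-12)
  }

  # constant trace -> zero OD; tenfold dip -> OD 1 at that sample
  const <- ri
  const$intensities[] <- 5
  expect_true(all(intensity_to_od(const) == 0))
  dip <- const
  nt <- dim(dip$intensities)[3]
  dip$intensities[1, 1, 100] <- 5 / 10
  od_dip <- intensity_to_od(dip)
  ibar <- mean(dip$intensities[1, 1, ])
  expect_equal(od_dip[1, 1, 100], -log10(0.5 / ibar), tolerance = 1e-12)

  neg <- ri
  neg$intensities[3, 2, 17] <- 0
  expect_error(intensity_to_od(neg), "channel 3", class = "rsfnirs_invalid_input")
})

test_that("band-pass passes the hemodynamic band and rejects noise and drift", {
  t <- (seq_len(2222) - 1) / fs
  cen <- seq(round(2222 * 0.1), round(2222 * 0.9))

  tone <- sin(2 * pi * 0.05 * t)
  out <- bandpass(tone, fs)
  expect_lt(abs(max(abs(out[cen])) - 1), 0.1)

  cardiac <- sin(2 * pi * 1.2 * t)
  expect_lt(sqrt(mean(bandpass(cardiac, fs)^2)), 0.1 * sqrt(mean(cardiac^2)))

  ramp <- seq(0, 1, length.out = 2222)
  out_r <- bandpass(ramp, fs)
  expect_lt(sqrt(mean(out_r[cen]^2)), 0.05 * sqrt(mean(ramp[cen]^2)))

  # >= 20 dB at half the lower edge and twice the upper edge
  for (f0 in c(0.01, 0.2)) {
    s <- sin(2 * pi * f0 * t)
    expect_lt(sqrt(mean(bandpass(s, fs)[cen]^2)), 0.1 * sqrt(mean(s^2)))
  }

  expect_error(bandpass(rnorm(10), fs), class = "rsfnirs_invalid_input")
  expect_error(bandpass(rnorm(1000), fs = 0.15), class = "rsfnirs_invalid_parameter")
})

test_that("wavelet transform reconstructs perfectly and despiking is surgical", {
  filt <- rsfnirs:::dwt_filter()
  expect_equal(sum(filt$h), sqrt(2), tolerance = 1e-12)
  x <- rnorm(512)
  dec <- rsfnirs:::dwt_periodized(x, 4, filt)
  expect_equal(rsfnirs:::idwt_periodized(dec, filt), x, tolerance = 1e-12)

  set.seed(31)
  clean <- bandpass(rnorm(2222), fs)
  y <- wavelet_despike(clean)
  expect_length(y, 2222)
  expect_gt(cor(clean, y), 0.99)

  spiked <- clean
  spiked[700] <- spiked[700] + 10 * sd(clean)
  z <- wavelet_despike(spiked)
  expect_lt(max(abs(z - clean)), 0.3 * max(abs(spiked - clean)))

  expect_identical(wavelet_despike(numeric(128)), numeric(128))
  expect_equal(length(wavelet_despike(clean[1:999])), 999)  # odd length
  expect_error(wavelet_despike(c(rnorm(100), NA)), class = "rsfnirs_invalid_input")
  expect_error(wavelet_despike(rnorm(10)), class = "rsfnirs_invalid_input")
})

test_that("MBLL inversion is linear and exact on constructed inputs", {
  ext <- default_extinction()
  expect_equal(dim(ext), c(2L, 2L))
  oxy <- matrix(rnorm(5 * 200, sd = 1e-3), 5, 200)
  deoxy <- matrix(rnorm(5 * 200, sd = 5e-4), 5, 200)
  d_cm <- 3; dpf <- 6.53
  od <- array(0, c(5, 2, 200))
  for (w in 1:2) od[, w, ] <- (ext[w, 1] * oxy + ext[w, 2] * deoxy) * d_cm * dpf
  rec <- mbll(od, mbll_params(dpf = dpf, separation_mm = 30, extinction = ext))
  expect_equal(rec$oxy$values, oxy, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rec$deoxy$values, deoxy, tolerance = 1e-9, ignore_attr = TRUE)

  # zero in, zero out; scaling OD scales both chromophores
  expect_true(all(mbll(od * 0)$oxy$values == 0))
  rec3 <- mbll(od * 3, mbll_params(dpf = dpf, extinction = ext))
  expect_equal(rec3$oxy$values, 3 * oxy, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(mbll_params(extinction = matrix(c(1, 1, 1, 1), 2)),
               class = "rsfnirs_configuration_error")
})

test_that("full preprocessing recovers planted connectivity end to end", {
  gt <- block_truth(0.8)
  acc <- matrix(0, 22, 22)
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    hb <- simulate_hb(gt, duration_s = 120, noise = noise_spec_silent(),
                      seed = 100 + s)
    out <- preprocess_subject(hb_to_intensity(hb))
    acc <- acc + cor_matrix(out)$values
  }
  acc <- acc / n_seeds
  # doubled bound for the shorter recording used here (120 s vs 300 s)
  expect_lt(mean(abs(acc - gt$correlation)[upper.tri(acc)]), 0.10)
  expect_false(is.null(attr(preprocess_subject(hb_to_intensity(
    simulate_hb(gt, duration_s = 60, seed = 1))), "deoxy")))
})

test_that("preprocessing is deterministic and robust to planted motion spikes", {
  gt <- block_truth(0.8)
  spiky <- noise_spec(spike_rate_per_min = 5, spike_amplitude_sd = 5e-3)
  err_clean <- err_spiky <- numeric(6)
  for (s in 1:6) {
    hb_c <- simulate_hb(gt, duration_s = 120, noise = noise_spec_silent(),
                        seed = 500 + s)
    hb_s <- simulate_hb(gt, duration_s = 120, noise = spiky, seed = 500 + s)
    cm_c <- cor_matrix(preprocess_subject(hb_to_intensity(hb_c)))$values
    cm_s <- cor_matrix(preprocess_subject(hb_to_intensity(hb_s)))$values
    err_clean[s] <- mean(abs(cm_c - gt$correlation)[upper.tri(cm_c)])
    err_spiky[s] <- mean(abs(cm_s - gt$correlation)[upper.tri(cm_s)])
  }
  expect_lt(mean(err_spiky), 2 * mean(err_clean))

  ri <- hb_to_intensity(simulate_hb(gt, duration_s = 60, seed = 3))
  expect_identical(preprocess_subject(ri)$values, preprocess_subject(ri)$values)
})
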