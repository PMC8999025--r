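test_that("block correlation ground truth has the requested structure", {
  gt <- make_block_correlation(within_r = 0.8, between_r = 0.3)
  C <- gt$correlation
  expect_equal(C[19, 20], 0.8)  # within OFC
  expect_equal(C[1, 19], 0.3)   # dlPFC x OFC
  expect_identical(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 22))
  expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)

  id <- make_block_correlation(within_r = 0, between_r = 0)
  expect_equal(unname(id$correlation), diag(22))

  expect_error(make_block_correlation(within_r = 0.3, between_r = 0.5),
               class = "rsfnirs_invalid_parameter")
  expect_error(make_block_correlation(within_r = 1, between_r = 0),
               class = "rsfnirs_invalid_parameter")
})

test_that("non-PSD block matrices are repaired to valid correlations", {
  # strongly negative between-block correlation on three blocks cannot be PSD
  gt <- make_block_correlation(within_r = 0.9, between_r = -0.6)
  ev <- eigen(gt$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)
  expect_equal(unname(diag(gt$correlation)), rep(1, 22))
  expect_true(all(abs(gt$correlation) <= 1 + 1e-12))
})

test_that("simulated recordings are deterministic in the seed", {
  gt <- block_truth(0.8)
  a <- simulate_hb(gt, duration_s = 60, seed = 11)
  b <- simulate_hb(gt, duration_s = 60, seed = 11)
  c <- simulate_hb(gt, duration_s = 60, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  # seeding does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(simulate_hb(gt, duration_s = 60, seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("a perfectly correlated one-block truth yields identical channels", {
  gt <- ground_truth(matrix(1, 22, 22))
  hb <- simulate_hb(gt, duration_s = 120, noise = noise_spec_silent(), seed = 4)
  cm <- cor_matrix(hb)$values
  expect_true(all(cm[upper.tri(cm)] >= 0.999))
})

test_that("noise-free empirical correlations converge to the planted truth", {
  gt <- make_block_correlation(within_r = 0, between_r = 0)  # identity
  per_seed_mad <- numeric(5)
  for (s in 1:5) {
    cm <- cor_matrix(simulate_hb(gt, noise = noise_spec_silent(), seed = s))$values
    per_seed_mad[s] <- mean(abs(cm[upper.tri(cm)]))
  }
  expect_true(all(per_seed_mad <= 0.15))  # band-limited sampling-error bound

  gt2 <- block_truth(0.8)
  acc <- matrix(0, 22, 22)
  for (s in 1:20)
    acc <- acc + cor_matrix(simulate_hb(gt2, noise = noise_spec_silent(),
                                        seed = s))$values
  acc <- acc / 20
  expect_lt(mean(abs(acc - gt2$correlation)[upper.tri(acc)]), 0.05)
})

test_that("forward optical model inverts exactly and scales with DPF", {
  gt <- block_truth(0.7)
  hb <- simulate_hb(gt, duration_s = 60, seed = 2)

  # zero concentration change -> intensity pinned at baseline
  zero <- hb_timeseries(matrix(0, 22, 444), fs_hz = 7.4074)
  ri0 <- hb_to_intensity(zero, baseline_intensity = 2.5)
  expect_true(all(ri0$intensities == 2.5))

  ri <- hb_to_intensity(hb)
  rec <- mbll(intensity_to_od(ri, reference = "baseline"), fs_hz = hb$fs_hz)
  expect_lt(max(abs(rec$oxy$values - hb$values)), 1e-9)
  expect_lt(max(abs(rec$deoxy$values)), 1e-9)

  # doubling DPF doubles the optical-density excursion (forward linearity)
  od1 <- intensity_to_od(hb_to_intensity(hb, dpf = 6.53), reference = "baseline")
  od2 <- intensity_to_od(hb_to_intensity(hb, dpf = 13.06), reference = "baseline")
  expect_equal(od2, 2 * od1, tolerance = 1e-10)

  expect_error(hb_to_intensity(hb, baseline_intensity = 0),
               class = "rsfnirs_invalid_parameter")
})

test_that("paired cohorts are reproducible and carry the paired structure", {
  tp <- block_truth(0.8); tq <- block_truth(0.6)
  coh1 <- generate_paired_cohort(3, tp, tq, duration_s = 60, seed = 9)
  coh2 <- generate_paired_cohort(3, tp, tq, duration_s = 60, seed = 9)
  expect_identical(coh1$subjects[[2]]$post$values, coh2$subjects[[2]]$post$values)
  expect_length(coh1$subjects, 3)
  for (s in coh1$subjects) {
    expect_equal(s$pre$session, "pre")
    expect_equal(s$post$session, "post")
    expect_equal(s$pre$fs_hz, s$post$fs_hz)
  }
  # subjects are distinct realizations
  expect_false(identical(coh1$subjects[[1]]$pre$values,
                         coh1$subjects[[2]]$pre$values))
  expect_error(generate_paired_cohort(1, tp, tq, duration_s = 60, seed = 1),
               class = "rsfnirs_invalid_parameter")
})

test_that("a planted connectivity decrease shows in group mean connectivity", {
  mats <- cohort_cor_mats(5, block_truth(0.8), block_truth(0.5),
                          duration_s = 120, seed = 21)
  pre <- mean_cor_scalar(group_mean_cor(mats$pre))
  post <- mean_cor_scalar(group_mean_cor(mats$post))
  expect_gt(pre, post)
})
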