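complete_net <- function(n) binary_network(matrix(1L, n, n) - diag(n))
star_net <- function(n) {
  A <- matrix(0L, n, n); A[1, 2:n] <- 1L; A[2:n, 1] <- 1L
  binary_network(A)
}
p3 <- binary_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))

test_that("metrics reproduce closed-form values on canonical graphs", {
  expect_equal(clustering_coefficient(complete_net(4)), 1)
  expect_equal(clustering_coefficient(star_net(5)), 0)
  expect_equal(global_efficiency(complete_net(5)), 1)
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(global_efficiency(binary_network(matrix(0L, 4, 4))), 0)
  expect_equal(char_path_length(complete_net(4)), 1)
  expect_equal(char_path_length(p3), 4 / 3)
  expect_true(is.na(char_path_length(binary_network(matrix(0L, 4, 4)))))

  # two disjoint edges: only connected pairs count
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  expect_equal(char_path_length(binary_network(A)), 1)

  le <- local_efficiency(complete_net(4))
  expect_equal(unname(le$nodal), rep(1, 4))
  expect_equal(local_efficiency(star_net(5))$mean, 0)

  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(star_net(6))[2:6]), rep(0, 5))
  # halved convention available
  expect_equal(unname(betweenness_centrality(p3, ordered = FALSE))[2], 0.5)
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(53)
  for (rep_i in 1:12) {
    A <- random_adjacency(6, runif(1, 0.2, 0.7))
    net <- binary_network(A)
    expect_equal(clustering_coefficient(net), oracle_clustering(A), tolerance = 1e-12)
    expect_equal(global_efficiency(net), oracle_global_eff(A), tolerance = 1e-12)
    expect_equal(char_path_length(net), oracle_lp(A), tolerance = 1e-12)
    expect_equal(unname(local_efficiency(net)$nodal), oracle_local_eff(A)$nodal,
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("nodal metrics are equivariant under node relabeling", {
  set.seed(59)
  A <- random_adjacency(8, 0.4)
  perm <- sample(8)
  Ap <- A[perm, perm]
  expect_equal(unname(betweenness_centrality(binary_network(Ap))),
               unname(betweenness_centrality(binary_network(A)))[perm],
               tolerance = 1e-12)
  expect_equal(unname(local_efficiency(binary_network(Ap))$nodal),
               unname(local_efficiency(binary_network(A))$nodal)[perm],
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(binary_network(Ap)),
               clustering_coefficient(binary_network(A)), tolerance = 1e-12)
})

test_that("density thresholding keeps the strongest edges, nested across T", {
  set.seed(61)
  M <- stats::cov2cor(crossprod(matrix(rnorm(484 * 2), ncol = 22)))
  cm <- connectivity_matrix(M)
  expect_equal(sum(density_threshold(cm, 0.9)$adjacency) / 2, floor(0.9 * 231))
  expect_equal(sum(density_threshold(cm, 1 / 231 - 1e-6)$adjacency), 0)
  prev <- NULL
  for (T in seq(0.1, 0.9, by = 0.1)) {
    a <- density_threshold(cm, T)$adjacency
    expect_equal(sum(a) / 2, floor(T * 231))
    if (!is.null(prev)) expect_true(all(prev <= a))
    prev <- a
  }
  expect_error(density_threshold(cm, 0), class = "rsfnirs_invalid_parameter")
  expect_error(density_threshold(cm, 1), class = "rsfnirs_invalid_parameter")

  # deterministic lexicographic tie-break at the cut
  tied <- diag(4)
  tied[upper.tri(tied)] <- 0.5
  tied <- tied + t(tied) - diag(diag(tied))
  net <- density_threshold(connectivity_matrix(tied), 0.5)  # 3 of 6 pairs
  # row-major lexicographic tie-break keeps (1,2), (1,3), (1,4)
  expect_equal(unname(rowSums(net$adjacency)), c(3, 1, 1, 1))
  expect_equal(unname(net$adjacency[1, ]), c(0L, 1L, 1L, 1L))
})

test_that("degree-preserving rewiring keeps degrees and is seed-deterministic", {
  set.seed(67)
  A <- random_adjacency(22, 0.3)
  net <- binary_network(A)
  r1 <- rewire_preserving_degree(net, seed = 5)
  r2 <- rewire_preserving_degree(net, seed = 5)
  r3 <- rewire_preserving_degree(net, seed = 6)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_false(identical(r1$adjacency, r3$adjacency))
  expect_equal(rowSums(r1$adjacency), rowSums(A), ignore_attr = TRUE)
  expect_equal(unname(diag(r1$adjacency)), rep(0L, 22))

  tri <- complete_net(3)  # K3 admits no swap
  expect_identical(rewire_preserving_degree(tri, seed = 1)$adjacency,
                   tri$adjacency)
  single <- binary_network(rbind(c(0L, 1L), c(1L, 0L)))
  out <- rewire_preserving_degree(single, seed = 1)
  expect_true(isTRUE(attr(out, "unswappable")))
})

test_that("self-similar nulls give gamma near one", {
  # an Erdos-Renyi graph is statistically its own degree-preserving null
  g <- igraph::sample_gnp(22, 0.3, directed = FALSE)
  withr_seed <- 2
  net <- binary_network(as.matrix(igraph::as_adjacency_matrix(g)))
  sw <- small_worldness(net, n_null = 100, seed = withr_seed)
  expect_true(sw$defined)
  expect_lt(abs(sw$gamma - 1), 0.15)
})

test_that("metric sweep profiles behave monotonically and AUC is calibrated", {
  set.seed(73)
  M <- stats::cov2cor(crossprod(matrix(rnorm(484 * 2), ncol = 22)))
  prof <- metric_sweep(connectivity_matrix(M))
  expect_equal(prof$scalar$T, seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(prof$scalar$Eglobal) >= -1e-12))
  expect_true(all(prof$scalar$Cnet >= 0 & prof$scalar$Cnet <= 1))
  expect_equal(dim(prof$nodal_bc), c(9L, 22L))

  # trapezoid AUC of a constant profile returns the constant
  expect_equal(rsfnirs:::trapezoid_mean(seq(0.1, 0.9, 0.1), rep(0.4, 9)), 0.4)
  expect_equal(rsfnirs:::trapezoid_mean(seq(0.1, 0.9, 0.1),
                                        c(NA, rep(0.4, 8))), 0.4)

  # planted modular structure inflates clustering over degree-matched nulls
  gt <- block_truth(0.8)
  cmats <- lapply(1:6, function(s)
    cor_matrix(simulate_hb(gt, duration_s = 120, seed = 300 + s)))
  gm <- group_mean_cor(cmats)
  sw <- small_worldness(density_threshold(gm, 0.3), n_null = 50, seed = 9)
  expect_gt(sw$gamma, 1)
})

test_that("nodal group comparison flags planted ROI-specific changes", {
  sweep3 <- c(0.2, 0.3, 0.4)
  gt <- block_truth(0.8)
  profs <- lapply(1:4, function(s) metric_sweep(
    cor_matrix(simulate_hb(gt, duration_s = 60, seed = 400 + s)), sweep3))
  same <- nodal_group_comparison(profs, profs, "betweenness")
  expect_equal(nrow(same), 22)
  expect_equal(same$channel, sprintf("CH%02d", 1:22))
  expect_true(all(same$t == 0 & same$p == 1))
  expect_false(any(same$significant))

  # OFC-only connectivity drop: OFC nodes should carry larger |t| on average
  pre_t <- make_block_correlation(within_r = 0.85, between_r = 0.2)
  post_c <- pre_t$correlation
  ofc <- roi_partition()$OFC
  post_c[ofc, ofc] <- 0.3
  diag(post_c) <- 1
  post_t <- ground_truth(post_c)
  diffs <- numeric(3)
  for (r in 1:3) {
    mats <- cohort_cor_mats(12, pre_t, post_t, duration_s = 120,
                            seed = 700 + r, noise = noise_spec_silent())
    pp <- lapply(mats$pre, metric_sweep, thresholds = sweep3)
    qq <- lapply(mats$post, metric_sweep, thresholds = sweep3)
    cmp <- nodal_group_comparison(pp, qq, "nodal_eloc")
    diffs[r] <- mean(abs(cmp$t[ofc])) - mean(abs(cmp$t[-ofc]))
  }
  expect_gt(mean(diffs), 0)
})
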