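test_that("ring lattice substrate has the analytic clustering coefficient", {
  net <- make_ground_truth_network(20, 4, rewiring_p = 0, seed = 7)
  topo <- (net$adjacency > 0) * 1
  # k = 4 ring lattice: C = 3(k-2) / (4(k-1)) = 0.5
  expect_equal(weighted_clustering(topo)$mean, 0.5, tolerance = 1e-12)
  expect_true(all(rowSums(topo) == 4))
})

test_that("full rewiring approaches the random-graph clustering level", {
  cc <- vapply(1:200, function(s) {
    net <- make_ground_truth_network(20, 4, rewiring_p = 1, seed = s)
    weighted_clustering((net$adjacency > 0) * 1)$mean
  }, numeric(1))
  # Erdos-Renyi expectation at this density is ~ k/n = 0.2
  expect_lt(abs(mean(cc) - 0.2), 0.05)
})

test_that("clustering degrades monotonically with rewiring", {
  c_low <- weighted_clustering(
    (make_ground_truth_network(20, 4, 0.05, seed = 7)$adjacency > 0) * 1)$mean
  c_high <- weighted_clustering(
    (make_ground_truth_network(20, 4, 0.6, seed = 7)$adjacency > 0) * 1)$mean
  expect_gt(c_low, c_high)
})

test_that("ground-truth network satisfies its structural invariants", {
  net <- make_ground_truth_network(15, 4, 0.3, weight_scale = 2, seed = 1)
  A <- net$adjacency
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0))
  w <- A[upper.tri(A)][A[upper.tri(A)] > 0]
  expect_true(all(w >= 1 & w <= 2))              # uniform(0.5,1) * scale 2
  expect_equal(net$lag, -t(net$lag))             # antisymmetric lags
  lg <- abs(net$lag[upper.tri(net$lag)][A[upper.tri(A)] > 0])
  expect_true(all(lg >= pi / 8 & lg <= 3 * pi / 8))
  expect_error(make_ground_truth_network(4, 4, 0.1), "n_nodes > neighbors_k")
  expect_error(make_ground_truth_network(10, 3, 0.1), "even")
})

test_that("a strongly coupled quarter-cycle-lagged pair approaches wPLI 1", {
  net <- structure(list(
    n_nodes = 2L, adjacency = matrix(c(0, 1, 1, 0), 2),
    lag = matrix(c(0, pi / 2, -pi / 2, 0), 2),
    topology_params = list()), class = "ground_truth_network")
  es <- simulate_oscillator_epochs(net, default_bands("alpha"),
                                   n_trials = 40, noise_sd_uv = 0.01,
                                   evoked_uv = 0, lag_jitter_kappa = 50,
                                   seed = 3)
  w <- subject_connectivity(es, "pooled")
  expect_gt(w[1, 2], 0.9)
})

test_that("uncoupled channels stay at the estimator noise floor", {
  net <- structure(list(
    n_nodes = 4L, adjacency = matrix(0, 4, 4), lag = matrix(0, 4, 4),
    topology_params = list()), class = "ground_truth_network")
  es <- simulate_oscillator_epochs(net, default_bands("alpha"),
                                   n_trials = 30, evoked_uv = 0, seed = 4)
  w <- subject_connectivity(es, "pooled")
  # the narrowband pooled-sample null floor at 30 trials: the pair average
  # sits below 0.15 and no single pair approaches coupled-pair levels
  expect_lt(mean(w[upper.tri(w)]), 0.15)
  expect_true(all(w[upper.tri(w)] < 0.25))
})

test_that("injected transients hit the amplitude rule at the binomial rate", {
  net <- structure(list(
    n_nodes = 3L, adjacency = matrix(0, 3, 3), lag = matrix(0, 3, 3),
    topology_params = list()), class = "ground_truth_network")
  es <- simulate_oscillator_epochs(net, default_bands("alpha"),
                                   n_trials = 50, artifact_rate = 0.2,
                                   seed = 5)
  n_bad <- sum(apply(abs(es$data), 1, max) > 200)
  # binomial(50, 0.2): central 99% interval roughly [3, 18]
  expect_gte(n_bad, 3)
  expect_lte(n_bad, 18)
})

test_that("epoch simulation is bit-identical under a fixed seed", {
  net <- make_ground_truth_network(6, 2, 0.2, seed = 1)
  e1 <- simulate_oscillator_epochs(net, default_bands("theta"),
                                   n_trials = 4, seed = 99)
  e2 <- simulate_oscillator_epochs(net, default_bands("theta"),
                                   n_trials = 4, seed = 99)
  expect_identical(e1$data, e2$data)
  expect_error(simulate_oscillator_epochs(net, default_bands()[0, ],
                                          n_trials = 2), "empty band")
})

test_that("wPLI rises monotonically with planted coupling strength", {
  # one band, star-free design: disjoint coupled pairs with increasing w
  n <- 10
  A <- matrix(0, n, n); L <- matrix(0, n, n)
  ws <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  for (k in seq_along(ws)) {
    i <- 2 * k - 1; j <- 2 * k
    A[i, j] <- A[j, i] <- ws[k]
    L[i, j] <- pi / 4; L[j, i] <- -pi / 4
  }
  net <- structure(list(n_nodes = as.integer(n), adjacency = A, lag = L,
                        topology_params = list()),
                   class = "ground_truth_network")
  rhos <- vapply(1:5, function(s) {
    es <- simulate_oscillator_epochs(net, default_bands("alpha"),
                                     n_trials = 30, evoked_uv = 0, seed = s)
    w <- subject_connectivity(es, "pooled")
    est <- vapply(seq_along(ws), function(k) w[2 * k - 1, 2 * k], numeric(1))
    stats::cor(est, ws, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.8)
})

test_that("planted behavior links IES to phi as configured", {
  bp <- list(base_ies_ms = 2600, slope_ies_vs_phi = 0, rt_noise_sd_ms = 1e-6,
             accuracy_logit = c(intercept = 50, slope = 0))
  phi <- stats::setNames(seq(0.3, 0.9, length.out = 10), paste0("s", 1:10))
  beh <- simulate_behavior(phi, bp, n_trials = 30, seed = 1)
  ies <- compute_ies(beh)
  # slope 0, vanishing noise: regression recovers a null slope
  f <- robust_regress(ies$ies_ms, phi[ies$subject_id])
  expect_lt(abs(f$slope), 1)
  # perfect accuracy: IES equals mean RT identically
  expect_equal(ies$ies_ms, ies$mean_rt_correct_ms)
  expect_true(all(beh$rt_ms > 0))
  # impossible accuracy parameters are rejected
  bad <- bp; bad$accuracy_logit <- c(intercept = -Inf, slope = 0)
  expect_error(simulate_behavior(phi, bad, 10, seed = 1), "accuracy")
})

test_that("cohort generation is reproducible and records the planted contrast", {
  cfg <- default_cohort_config(
    n_subjects = c(control = 2, dd = 2), bands = "theta",
    epochs_per_subject = list(control = c(mean = 5, sd = 0),
                              dd = c(mean = 5, sd = 0)),
    n_channels = 8, phi_null_models = 5, seed = 3)
  t1 <- make_cohort_truth(cfg)
  t2 <- make_cohort_truth(cfg)
  expect_identical(t1$networks, t2$networks)
  e1 <- simulate_cohort_epochs(t1)
  e2 <- simulate_cohort_epochs(t2)
  expect_identical(e1$control[[1]]$word$data, e2$control[[1]]$word$data)
  expect_equal(t1$planted_contrast$rewiring_p[["control"]], 0.1)
  expect_equal(t1$planted_contrast$rewiring_p[["dd"]], 0.5)
  # config round-trips through YAML
  p <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, p)
  expect_equal(read_cohort_config(p)[names(cfg)], cfg)
})
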