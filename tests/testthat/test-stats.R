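test_that("Kruskal-Wallis reproduces hand-ranked values and invariances", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$chi2,
               3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$chi2, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)
  # rank invariance under strictly monotone transforms
  x <- list(stats::rnorm(8), stats::rnorm(8) + 1)
  expect_equal(kruskal_wallis(x)$chi2,
               kruskal_wallis(lapply(x, exp))$chi2, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("global permutation test matches exhaustive enumeration", {
  x <- c(1.2, 0.3, 2.1); y <- c(4.5, 3.8, 5.0)
  ex <- permutation_test_global(x, y, exact = TRUE)
  expect_equal(ex$n_perm, 20)
  expect_equal(ex$p, 2 / 20)              # only the two extreme splits
  # identical groups: everything ties, p = 1
  same <- permutation_test_global(c(1, 1, 1), c(1, 1, 1), exact = TRUE)
  expect_equal(same$p, 1)
  mc <- permutation_test_global(x, y, n_perm = 2000, seed = 1)
  expect_lt(abs(mc$p - ex$p), 0.03)
  expect_warning(permutation_test_global(x, y, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("multiple-testing thresholds and decisions are correct", {
  b3 <- adjust_multiple(c(0.01, 0.02, 0.03), "bonferroni", alpha = 0.05, m = 3)
  expect_equal(b3$threshold, 0.05 / 3)
  expect_equal(b3$significant, c(TRUE, FALSE, FALSE))
  expect_equal(b3$p_adjusted, c(0.03, 0.06, 0.09))
  b2 <- adjust_multiple(0.02, "bonferroni", alpha = 0.05, m = 2)
  expect_equal(b2$threshold, 0.025)
  # BH step-up: thresholds 0.0167 / 0.0333 / 0.05 admit all three
  bh <- adjust_multiple(c(0.01, 0.02, 0.04), "bh", q = 0.05)
  expect_true(all(bh$significant))
  expect_error(adjust_multiple(0.5, "bonferroni", m = 0), "positive")
})

test_that("Bonferroni is never more liberal than Benjamini-Hochberg", {
  set.seed(30)
  for (i in 1:20) {
    p <- stats::runif(10)^2
    bf <- adjust_multiple(p, "bonferroni", alpha = 0.05)
    bh <- adjust_multiple(p, "bh", q = 0.05)
    expect_true(all(!bf$significant | bh$significant))
  }
})

test_that("cluster-mass test finds planted effects and nothing else", {
  nb <- montage_neighbors()
  labs <- rownames(nb)
  set.seed(31)
  # sub-threshold everywhere: zero clusters
  a <- matrix(stats::rnorm(12 * 40, sd = 0.01), 12, 40,
              dimnames = list(NULL, labs))
  b <- a + stats::rnorm(480, sd = 0.01)
  quiet <- cluster_mass_permutation(a, a + 1e-6, nb, n_perm = 100, seed = 1)
  expect_length(quiet$clusters, 0)
  # large planted effect on four adjacent sensors is recovered
  planted <- c("C1", "Cz", "C2", "FC1")
  hits <- vapply(1:10, function(s) {
    a <- matrix(stats::rnorm(12 * 40), 12, 40, dimnames = list(NULL, labs))
    b <- matrix(stats::rnorm(12 * 40), 12, 40, dimnames = list(NULL, labs))
    a[, planted] <- a[, planted] + 3
    cm <- cluster_mass_permutation(a, b, nb, n_perm = 300, seed = s)
    sig <- unlist(lapply(cm$clusters, function(cl)
      if (cl$p_corrected < 0.05) cl$members))
    sum(planted %in% sig)
  }, numeric(1))
  expect_gte(mean(hits >= 3), 0.9)
  expect_error(cluster_mass_permutation(a, b, matrix(FALSE, 40, 40)),
               "neighbor graph")
})

test_that("permutation procedures are reproducible and exchangeable", {
  set.seed(32)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  p1 <- permutation_test_global(x, y, n_perm = 300, seed = 7)$p
  p2 <- permutation_test_global(x, y, n_perm = 300, seed = 7)$p
  expect_identical(p1, p2)
  # the exhaustive test is exactly exchangeable under subject reordering
  e1 <- permutation_test_global(x[1:4], y[1:4], exact = TRUE)$p
  e2 <- permutation_test_global(x[4:1], y[c(2, 1, 4, 3)], exact = TRUE)$p
  expect_identical(e1, e2)
})

test_that("IES follows its defining ratio", {
  rec <- data.frame(subject_id = "s1", condition = "word",
                    rt_ms = rep(1000, 10),
                    correct = rep(c(TRUE, FALSE), c(8, 2)))
  expect_equal(compute_ies(rec)$ies_ms, 1250)          # 1000 / 0.8
  rec$correct <- TRUE
  expect_equal(compute_ies(rec)$ies_ms, 1000)          # identity at p = 1
  # halving accuracy at fixed RT doubles IES
  rec2 <- data.frame(subject_id = "s1", condition = "word",
                     rt_ms = rep(1000, 10),
                     correct = rep(c(TRUE, FALSE), each = 5))
  rec2$rt_ms[!rec2$correct] <- 999    # only correct trials enter the mean
  rec2$rt_ms[rec2$correct] <- 1000
  expect_equal(compute_ies(rec2)$ies_ms, 2000)
  none <- data.frame(subject_id = "s1", condition = "word",
                     rt_ms = 500, correct = FALSE)
  expect_false(compute_ies(none)$defined)
})

test_that("robust regression resists gross outliers", {
  set.seed(33)
  phi <- stats::runif(20, 0.4, 0.9)
  y <- -2000 * phi + 1500
  clean <- robust_regress(y, phi)
  expect_equal(clean$slope, -2000, tolerance = 1e-6)
  expect_equal(clean$adjusted_r2, 1)
  y_out <- y; y_out[1] <- y_out[1] + 5000
  rob <- robust_regress(y_out, phi)
  ols <- stats::coef(stats::lm(y_out ~ phi))[2]
  expect_lt(abs(rob$slope - (-2000)) / 2000, 0.1)
  expect_gt(abs(ols - (-2000)) / 2000, abs(rob$slope - (-2000)) / 2000)
  expect_error(robust_regress(y[1:10], rep(0.5, 10)), "zero variance")
  expect_error(robust_regress(y[1:4], phi[1:4]), "at least 5")
})

test_that("hemisphere comparison is symmetric and sign-consistent", {
  m <- standard_montage()
  set.seed(34)
  base <- matrix(stats::rnorm(10 * 40, mean = 5), 10, 40,
                 dimnames = list(NULL, m$label))
  # mirror-symmetric values: zero median difference
  for (lab in m$label[m$hemisphere == "L"]) {
    mirror <- sub("([A-Za-z]+)([0-9]+)", "\\1", lab)
    num <- as.integer(sub("^[A-Za-z]+", "", lab))
    rlab <- paste0(mirror, num + 1)
    if (rlab %in% m$label) base[, rlab] <- base[, lab]
  }
  hs <- hemisphere_median_compare(base, m)
  expect_equal(hs$median_diff, 0, tolerance = 1e-12)
  # doubling the left metric flips nothing but the sign on relabel
  lifted <- base
  lifted[, m$label[m$hemisphere == "L"]] <-
    2 * lifted[, m$label[m$hemisphere == "L"]]
  h2 <- hemisphere_median_compare(lifted, m)
  expect_gt(h2$median_diff, 0)
  expect_lt(h2$p, 0.05)
  flipped <- m
  flipped$hemisphere <- chartr("LR", "RL", flipped$hemisphere)
  h3 <- hemisphere_median_compare(lifted, flipped)
  expect_equal(h3$median_diff, -h2$median_diff)
  m2 <- m; m2$hemisphere[m2$hemisphere == "R"] <- "M"
  expect_error(hemisphere_median_compare(base, m2), "no sensors")
})
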