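triangle <- function(w = 1) {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- w
  a
}

star <- function(n = 5, w = 1) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- w
  a
}

complete_graph <- function(n, w = 1) {
  a <- matrix(w, n, n); diag(a) <- 0; a
}

path3 <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  a
}

test_that("weighted clustering matches its closed forms and the oracle", {
  expect_equal(weighted_clustering(triangle())$node, rep(1, 3))
  expect_equal(weighted_clustering(star())$node, rep(0, 5))
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3] <- a[3, 1] <- 0.5
  a[2, 3] <- a[3, 2] <- 0.25
  a[3, 4] <- a[4, 3] <- 1
  expect_equal(weighted_clustering(a)$node, oracle_clustering(a),
               tolerance = 1e-12)
  expect_error(weighted_clustering(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("characteristic path length follows the 1/w cost convention", {
  expect_equal(char_path_length(complete_graph(2))$L, 1)
  # path a-b-c, unit weights: pairs (1,1,2), L = 4/3
  expect_equal(char_path_length(path3())$L, 4 / 3)
  expect_equal(char_path_length(complete_graph(6, w = 0.5))$L, 2)
  # disconnected pair counting
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  expect_error(char_path_length(a), "unreachable")
})

test_that("lattice surrogate is a deterministic fixed point", {
  set.seed(20)
  a <- random_test_graph(8)
  latt <- lattice_surrogate(a)
  expect_identical(lattice_surrogate(latt), latt)     # idempotent
  expect_equal(sort(latt[upper.tri(latt)]), sort(a[upper.tri(a)]))
  nulls <- build_null_models(latt, n_random = 5, seed = 1)
  expect_equal(nulls$c_latt, weighted_clustering(latt)$mean)
})

test_that("equal-weight complete graphs are invariant under the random null", {
  a <- complete_graph(8)
  nulls <- build_null_models(a, n_random = 10, seed = 2)
  expect_equal(nulls$c_rand, weighted_clustering(a)$mean, tolerance = 1e-12)
  expect_equal(nulls$l_rand, char_path_length(a)$L, tolerance = 1e-12)
  expect_error(build_null_models(triangle()), "too small")
})

test_that("null ordering holds on small-world substrates", {
  ok <- vapply(1:20, function(s) {
    net <- make_ground_truth_network(30, 4, 0.1, seed = s)
    a <- net$adjacency
    nulls <- build_null_models(a, n_random = 10)
    c_obs <- weighted_clustering(a)$mean
    nulls$c_latt >= c_obs && c_obs >= nulls$c_rand
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("small-world propensity hits its canonical fixed points", {
  a <- complete_graph(5)
  # C_obs = C_latt and L_obs = L_rand: ideal small world, phi = 1
  nulls <- list(c_latt = weighted_clustering(a)$mean, l_latt = 3,
                c_rand = 0.1, l_rand = char_path_length(a)$L,
                n_random = 0)
  s1 <- small_world_propensity(a, nulls)
  expect_equal(s1$delta_c, 0); expect_equal(s1$delta_l, 0)
  expect_equal(s1$phi, 1)
  # C_obs = C_rand and L_obs = L_latt: maximal deviation, phi = 0
  nulls2 <- list(c_latt = 0.9, l_latt = char_path_length(a)$L,
                 c_rand = weighted_clustering(a)$mean, l_rand = 0.2,
                 n_random = 0)
  s2 <- small_world_propensity(a, nulls2)
  expect_equal(s2$delta_c, 1); expect_equal(s2$delta_l, 1)
  expect_equal(s2$phi, 0)
  # phi reproducible from stored deviations to machine precision
  expect_equal(s2$phi, 1 - sqrt((s2$delta_c^2 + s2$delta_l^2) / 2))
})

test_that("deviations are clamped and degenerate nulls warn", {
  a <- complete_graph(5)
  nulls <- list(c_latt = 0.5, l_latt = 2, c_rand = 0.5, l_rand = 0.5,
                n_random = 0)
  expect_warning(s <- small_world_propensity(a, nulls), "degenerate")
  expect_true(s$delta_c %in% c(0, 1))
  expect_true(all(c(s$phi, s$delta_c, s$delta_l) >= 0 &
                    c(s$phi, s$delta_c, s$delta_l) <= 1))
})

test_that("node strength and betweenness match closed forms", {
  s <- node_strength_bc(star(5))
  expect_equal(s$bc_raw, c(1, 0, 0, 0, 0))            # all geodesics via hub
  expect_equal(s$strength_raw, c(4, 1, 1, 1, 1))
  k <- node_strength_bc(complete_graph(6, 0.7))
  expect_equal(k$strength_norm, rep(1, 6))
  expect_equal(k$bc_norm, rep(0, 6))                  # no intermediaries
  expect_error(node_strength_bc(matrix(0, 2, 2)), "fewer than 3")
})

test_that("betweenness equals exhaustive enumeration on random graphs", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_test_graph(sample(5:7, 1))
    o <- oracle_graph_metrics(a)
    nm <- node_strength_bc(a)
    expect_equal(nm$bc_raw, o$node_bc, tolerance = 1e-9)
    expect_equal(char_path_length(a)$L, o$L, tolerance = 1e-9)
    expect_equal(edge_betweenness_bc(a), o$edge_bc, tolerance = 1e-9)
  }
})

test_that("hub detection applies the one-SD rule", {
  m <- rbind(c(1, 1, 1, 1, 3), c(1, 1, 1, 1, 3))
  h <- detect_hubs(m)
  expect_equal(h$threshold, 1.4 + stats::sd(c(1, 1, 1, 1, 3)))
  expect_equal(unname(which(h$hub)), 5)
  # translation invariance
  h2 <- detect_hubs(m + 10)
  expect_equal(h$hub, h2$hub)
  # zero spread: no hubs
  expect_warning(h3 <- detect_hubs(matrix(1, 2, 4)), "no hubs")
  expect_false(any(h3$hub))
})

test_that("edge importance flags bridges and ignores subject order", {
  # two 4-cliques joined by one bridge
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1; diag(a) <- 0
  a[4, 5] <- a[5, 4] <- 1
  eb <- edge_bc_table(edge_betweenness_bc(a))
  subj <- rbind(eb, eb * 1.01, eb * 0.99)
  imp <- edge_importance(subj)
  expect_true(imp$important[["n4|n5"]])
  expect_identical(edge_importance(subj[c(3, 1, 2), ])$important,
                   imp$important)
  # path graph: both present edges carry equal load, none important
  ebp <- edge_bc_table(edge_betweenness_bc(path3()))
  ip <- edge_importance(rbind(ebp, ebp))
  expect_false(any(ip$important))
  # zero spread across edges: warning, nothing flagged
  expect_warning(iz <- edge_importance(matrix(1, 2, 3)), "no hubs")
  expect_false(any(iz$important))
})

test_that("uniform weight scaling leaves all normalized measures unchanged", {
  set.seed(22)
  a <- random_test_graph(7)
  s1 <- small_world_propensity(a, n_random = 10, seed = 5)
  s2 <- small_world_propensity(a * 4.2, n_random = 10, seed = 5)
  expect_equal(s1$delta_c, s2$delta_c, tolerance = 1e-9)
  expect_equal(s1$delta_l, s2$delta_l, tolerance = 1e-9)
  expect_equal(s1$phi, s2$phi, tolerance = 1e-9)
  n1 <- node_strength_bc(a); n2 <- node_strength_bc(a * 4.2)
  expect_equal(n1$strength_norm, n2$strength_norm, tolerance = 1e-12)
  expect_equal(n1$bc_norm, n2$bc_norm, tolerance = 1e-12)
})
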