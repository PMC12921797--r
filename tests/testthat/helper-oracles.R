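# Independent brute-force oracles. These deliberately share no code with
# the package: clustering by explicit triangle loops, shortest paths by
# exhaustive simple-path enumeration, betweenness by counting geodesics.
# Tractable for graphs up to ~7 nodes.

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  w <- adj / max(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    cc[i] <- s / (k * (k - 1))
  }
  cc
}

# all simple paths s -> t as list of vertex vectors
oracle_all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (u in seq_len(n))
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
  }
  walk(s)
  paths
}

path_cost <- function(adj, p) {
  if (length(p) < 2) return(0)
  sum(1 / adj[cbind(p[-length(p)], p[-1])])
}

# distance matrix + node and edge betweenness by geodesic enumeration
oracle_graph_metrics <- function(adj, tol = 1e-9) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  node_bc <- numeric(n)
  edge_bc <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_paths(adj, s, t)
    if (length(paths) == 0) next
    costs <- vapply(paths, function(p) path_cost(adj, p), numeric(1))
    dmin <- min(costs)
    d[s, t] <- d[t, s] <- dmin
    geo <- paths[costs <= dmin + tol]
    ns <- length(geo)
    for (p in geo) {
      inner <- p[-c(1, length(p))]
      node_bc[inner] <- node_bc[inner] + 1 / ns
      for (e in seq_len(length(p) - 1)) {
        edge_bc[p[e], p[e + 1]] <- edge_bc[p[e], p[e + 1]] + 1 / ns
        edge_bc[p[e + 1], p[e]] <- edge_bc[p[e + 1], p[e]] + 1 / ns
      }
    }
  }
  list(dist = d,
       L = mean(d[upper.tri(d)][is.finite(d[upper.tri(d)])]),
       node_bc = node_bc / ((n - 1) * (n - 2) / 2),
       edge_bc = edge_bc / (n * (n - 1) / 2))
}

# random connected weighted graph on n nodes
random_test_graph <- function(n, p_edge = 0.6) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p_edge)
        adj[i, j] <- adj[j, i] <- stats::runif(1, 0.1, 1)
    # connectivity via reachability on the boolean pattern
    reach <- diag(n) + adj > 0
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    if (all(reach)) return(adj)
  }
}

# Independent reference implementation of the small-world propensity:
# Floyd-Warshall path lengths, loop-based clustering, own lattice and
# degree-preserving randomization. No package code used.
reference_swp <- function(adj, n_random = 50) {
  n <- nrow(adj)
  cmean <- function(a) mean(oracle_clustering(a))
  lmean <- function(a) {
    d <- 1 / a; d[a == 0] <- Inf; diag(d) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
      if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    off <- d[upper.tri(d)]
    mean(off[is.finite(off)])
  }
  # lattice: sorted weights onto smallest ring distances
  w <- sort(adj[upper.tri(adj)][adj[upper.tri(adj)] > 0], decreasing = TRUE)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  rd <- pmin(abs(pairs[, 1] - pairs[, 2]), n - abs(pairs[, 1] - pairs[, 2]))
  ord <- order(rd, pairs[, 1], pairs[, 2])
  latt <- matrix(0, n, n)
  sl <- pairs[ord[seq_along(w)], , drop = FALSE]
  latt[sl] <- w; latt[sl[, c(2, 1)]] <- w
  # random: own Maslov-Sneppen swaps + weight shuffle
  rand_one <- function() {
    el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    for (it in seq_len(10 * nrow(el))) {
      ij <- sample(nrow(el), 2)
      a <- el[ij[1], 1]; b <- el[ij[1], 2]
      c_ <- el[ij[2], 1]; d_ <- el[ij[2], 2]
      if (length(unique(c(a, b, c_, d_))) < 4) next
      # swap to (a,d) (c,b) if neither exists
      has <- function(x, y) any(el[, 1] == min(x, y) & el[, 2] == max(x, y))
      if (has(a, d_) || has(c_, b)) next
      el[ij[1], ] <- c(min(a, d_), max(a, d_))
      el[ij[2], ] <- c(min(c_, b), max(c_, b))
    }
    m <- matrix(0, n, n)
    ws <- sample(w)
    m[el] <- ws; m[el[, c(2, 1)]] <- ws
    m
  }
  cr <- lr <- numeric(n_random)
  for (i in seq_len(n_random)) {
    m <- rand_one()
    cr[i] <- cmean(m); lr[i] <- lmean(m)
  }
  c_obs <- cmean(adj); l_obs <- lmean(adj)
  c_latt <- cmean(latt); l_latt <- lmean(latt)
  dc <- min(1, max(0, (c_latt - c_obs) / (c_latt - mean(cr))))
  dl <- min(1, max(0, (l_obs - mean(lr)) / (l_latt - mean(lr))))
  list(phi = 1 - sqrt((dc^2 + dl^2) / 2), delta_c = dc, delta_l = dl)
}
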