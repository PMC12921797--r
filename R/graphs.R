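check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix")
  if (any(adj < 0)) stop("adjacency has negative weights")
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  adj <- (adj + t(adj)) / 2
  diag(adj) <- 0
  adj
}

adj_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# connection-to-distance convention for wPLI graphs: cost = 1 / weight
edge_costs <- function(g) 1 / igraph::E(g)$weight

#' Onnela weighted clustering coefficient
#'
#' Per-node weighted clustering with weights normalized by the matrix
#' maximum: `C_i = sum_(j,h) (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`,
#' where `k_i` counts nonzero connections; nodes with degree < 2 get 0.
#' High values mean dense, strongly weighted local triangles (functional
#' segregation).
#'
#' @param adj symmetric nonnegative matrix, zero diagonal.
#' @return list with `node` (per-node coefficients) and `mean`.
#' @export
weighted_clustering <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  mx <- max(adj)
  if (mx == 0) return(list(node = rep(0, n), mean = 0))
  W3 <- (adj / mx)^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(adj > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  list(node = as.numeric(cc), mean = mean(cc))
}

#' Weighted characteristic path length
#'
#' Shortest paths on edge costs `1/weight` (strong connections are short),
#' averaged over all reachable ordered pairs. Disconnected pairs are
#' excluded from the mean and counted.
#'
#' @param adj symmetric nonnegative matrix.
#' @return list with `L` (mean finite shortest-path length),
#'   `unreachable_pairs` (unordered count). Errors if more than half of all
#'   pairs are unreachable.
#' @export
char_path_length <- function(adj) {
  adj <- check_adjacency(adj)
  g <- adj_graph(adj)
  d <- igraph::distances(g, weights = edge_costs(g))
  off <- d[upper.tri(d)]
  bad <- sum(!is.finite(off))
  if (bad > length(off) / 2)
    stop("more than half of all node pairs are unreachable")
  list(L = mean(off[is.finite(off)]), unreachable_pairs = bad)
}

#' Lattice surrogate: weights sorted onto a ring lattice
#'
#' The regular-network null of the small-world propensity construction.
#' All `m` edge weights are placed onto the `m` ring-lattice slots with the
#' smallest ring distance, largest weights first. Slots are enumerated in a
#' fixed order — ring distance ascending, then row, then column — so the
#' surrogate is fully deterministic and the construction is idempotent: a
#' matrix already in sorted-lattice form is its own surrogate.
#'
#' @param adj symmetric nonnegative matrix.
#' @return The surrogate adjacency matrix.
#' @export
lattice_surrogate <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  ringd <- pmin(abs(ut[, 1] - ut[, 2]), n - abs(ut[, 1] - ut[, 2]))
  ord <- order(ringd, ut[, 1], ut[, 2])
  w <- sort(adj[upper.tri(adj)][adj[upper.tri(adj)] > 0], decreasing = TRUE)
  out <- matrix(0, n, n, dimnames = dimnames(adj))
  slots <- ut[ord[seq_along(w)], , drop = FALSE]
  out[slots] <- w
  out[cbind(slots[, 2], slots[, 1])] <- w
  out
}

#' Random surrogate: degree-preserving rewiring with weight reshuffle
#'
#' The random null: the binary connection pattern is rewired by
#' degree-preserving edge swaps (so the degree sequence is identical) and
#' the observed weights are then reassigned to the rewired edges in random
#' order. Uses the current RNG state.
#'
#' @param adj symmetric nonnegative matrix.
#' @param swaps_per_edge rewiring intensity (edge-swap attempts per edge).
#' @return A surrogate adjacency matrix.
#' @export
random_surrogate <- function(adj, swaps_per_edge = 10) {
  adj <- check_adjacency(adj)
  g <- adj_graph(adj)
  m <- igraph::ecount(g)
  if (nrow(adj) < 4) stop("graph too small for degree-preserving swaps")
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m))
  w <- sample(igraph::E(g)$weight)
  el <- igraph::as_edgelist(gr, names = FALSE)
  out <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  out[el] <- w
  out[el[, c(2, 1), drop = FALSE]] <- w
  out
}

#' Lattice and random null-model statistics
#'
#' Computes the clustering and path-length reference values the
#' small-world propensity normalizes against: the deterministic lattice
#' surrogate, and the average over `n_random` degree-preserving random
#' surrogates.
#'
#' @param adj symmetric nonnegative matrix (>= 4 nodes).
#' @param n_random number of random surrogates (100 in the reference
#'   procedure; reducible for speed).
#' @param seed optional integer seed.
#' @param metrics `"both"` (default), or `"clustering"` / `"path"` to skip
#'   the unneeded metric (path lengths dominate the cost) when only one
#'   deviation is analyzed.
#' @return list `c_latt`, `l_latt`, `c_rand`, `l_rand`, `n_random` (the
#'   skipped metric's entries are `NA`).
#' @export
build_null_models <- function(adj, n_random = 100, seed = NULL,
                              metrics = c("both", "clustering", "path")) {
  metrics <- match.arg(metrics)
  adj <- check_adjacency(adj)
  if (nrow(adj) < 4) stop("graph too small for null models (< 4 nodes)")
  if (!is.null(seed)) set.seed(seed)
  do_c <- metrics != "path"; do_l <- metrics != "clustering"
  latt <- lattice_surrogate(adj)
  cl <- if (do_c) weighted_clustering(latt)$mean else NA_real_
  ll <- if (do_l) char_path_length(latt)$L else NA_real_
  cr <- lr <- rep(NA_real_, n_random)
  for (i in seq_len(n_random)) {
    s <- random_surrogate(adj)
    if (do_c) cr[i] <- weighted_clustering(s)$mean
    if (do_l) lr[i] <- char_path_length(s)$L
  }
  list(c_latt = cl, l_latt = ll, c_rand = mean(cr), l_rand = mean(lr),
       n_random = n_random)
}

#' Clustering deviation from the lattice/random nulls
#'
#' Just the `dC` component of the small-world propensity, without the
#' path-length machinery — the quantity manipulated by the planted group
#' contrast, and much cheaper to compute alone.
#'
#' @inheritParams build_null_models
#' @return `dC` in \[0, 1\].
#' @export
clustering_deviation <- function(adj, n_random = 100, seed = NULL) {
  adj <- check_adjacency(adj)
  nulls <- build_null_models(adj, n_random, seed, metrics = "clustering")
  c_obs <- weighted_clustering(adj)$mean
  dev_ratio(nulls$c_latt - c_obs, nulls$c_latt - nulls$c_rand, "clustering")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# deviation ratio with the degenerate-null convention: 0/0 -> 0,
# x/0 -> clamped extreme, with a warning
dev_ratio <- function(num, den, what) {
  if (abs(den) < 1e-12) {
    if (abs(num) >= 1e-12)
      warning("degenerate null models for ", what, "; deviation clamped")
    return(if (abs(num) < 1e-12) 0 else clamp01(sign(num) * Inf))
  }
  clamp01(num / den)
}

#' Small-World Propensity
#'
#' Quantifies how closely a weighted network approaches the ideal
#' small-world balance of high clustering and short paths. The observed
#' clustering and path length are located between their lattice and random
#' null references:
#' `dC = (C_latt - C_obs) / (C_latt - C_rand)`,
#' `dL = (L_obs - L_rand) / (L_latt - L_rand)`,
#' both clamped to \[0, 1\], and
#' `phi = 1 - sqrt((dC^2 + dL^2) / 2)`.
#' `phi` near 1 means lattice-like clustering with random-like path length
#' (an efficient small world); large deviations drive `phi` toward 0.
#'
#' @param adj symmetric nonnegative matrix.
#' @param nulls optional precomputed result of [build_null_models()] for
#'   the same matrix.
#' @param n_random,seed forwarded to [build_null_models()] when `nulls` is
#'   missing.
#' @return object of class `swp_result`: `phi`, `delta_c`, `delta_l`, the
#'   observed and null clustering/path-length values, and `n_nulls`.
#' @export
small_world_propensity <- function(adj, nulls = NULL, n_random = 100,
                                   seed = NULL) {
  adj <- check_adjacency(adj)
  if (is.null(nulls)) nulls <- build_null_models(adj, n_random, seed)
  c_obs <- weighted_clustering(adj)$mean
  l_obs <- char_path_length(adj)$L
  dc <- dev_ratio(nulls$c_latt - c_obs, nulls$c_latt - nulls$c_rand, "clustering")
  dl <- dev_ratio(l_obs - nulls$l_rand, nulls$l_latt - nulls$l_rand, "path length")
  structure(
    list(phi = 1 - sqrt((dc^2 + dl^2) / 2), delta_c = dc, delta_l = dl,
         c_obs = c_obs, l_obs = l_obs,
         c_latt = nulls$c_latt, l_latt = nulls$l_latt,
         c_rand = nulls$c_rand, l_rand = nulls$l_rand,
         n_nulls = nulls$n_random),
    class = "swp_result")
}

#' @export
print.swp_result <- function(x, ...) {
  cat(sprintf("<swp_result> phi=%.4f  dC=%.4f  dL=%.4f  (n_nulls=%d)\n",
              x$phi, x$delta_c, x$delta_l, x$n_nulls))
  invisible(x)
}

#' Node strength and betweenness centrality
#'
#' Strength is the summed connection weight per node. Betweenness is the
#' proportion of all shortest paths (on `1/weight` costs, Brandes
#' algorithm) passing through the node, i.e. raw betweenness divided by
#' the `(n-1)(n-2)/2` pairs that could route through it. Both are also
#' returned normalized by their across-node mean, the per-subject scaling
#' used before hub detection.
#'
#' @param adj symmetric nonnegative matrix, >= 3 nodes.
#' @return data.frame: node, strength_raw, strength_norm, bc_raw, bc_norm.
#' @export
node_strength_bc <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  if (n < 3) stop("betweenness undefined for fewer than 3 nodes")
  strength <- rowSums(adj)
  g <- adj_graph(adj)
  bc <- rep(0, n)
  if (igraph::ecount(g) > 0)
    bc <- igraph::betweenness(g, weights = edge_costs(g), normalized = FALSE)
  bc <- bc / ((n - 1) * (n - 2) / 2)
  norm_by_mean <- function(v) if (mean(v) > 0) v / mean(v) else rep(0, length(v))
  labels <- rownames(adj)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  data.frame(node = labels,
             strength_raw = as.numeric(strength),
             strength_norm = norm_by_mean(as.numeric(strength)),
             bc_raw = as.numeric(bc),
             bc_norm = norm_by_mean(as.numeric(bc)),
             stringsAsFactors = FALSE)
}

#' Edge betweenness centrality matrix
#'
#' Proportion of all shortest paths (costs `1/weight`) running over each
#' edge; entries for absent edges are 0.
#'
#' @param adj symmetric nonnegative matrix.
#' @return symmetric `n x n` matrix of edge betweenness proportions.
#' @export
edge_betweenness_bc <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  g <- adj_graph(adj)
  out <- matrix(0, n, n, dimnames = dimnames(adj))
  if (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = edge_costs(g)) /
      (n * (n - 1) / 2)
    el <- igraph::as_edgelist(g, names = FALSE)
    out[el] <- eb
    out[el[, c(2, 1), drop = FALSE]] <- eb
  }
  out
}

one_sd_rule <- function(node_means) {
  thr <- mean(node_means) + stats::sd(node_means)
  if (stats::sd(node_means) == 0) {
    warning("zero variance across nodes: no hubs")
    return(list(flag = rep(FALSE, length(node_means)), threshold = thr))
  }
  list(flag = node_means >= thr, threshold = thr)
}

#' Hub detection by the one-standard-deviation rule
#'
#' A node is a hub when its metric, averaged across all participants, is at
#' least one (sample) standard deviation above the mean of those node
#' averages.
#'
#' @param metric_by_subject numeric matrix `subjects x nodes` (>= 2
#'   subjects), e.g. normalized strength or betweenness.
#' @return list: `hub` (named logical), `threshold`, `node_mean`.
#' @export
detect_hubs <- function(metric_by_subject) {
  stopifnot(is.matrix(metric_by_subject), nrow(metric_by_subject) >= 2)
  node_mean <- colMeans(metric_by_subject)
  r <- one_sd_rule(node_mean)
  hub <- r$flag
  names(hub) <- colnames(metric_by_subject)
  list(hub = hub, threshold = r$threshold, node_mean = node_mean)
}

#' Important-edge detection
#'
#' Same one-standard-deviation rule as [detect_hubs()], applied to edge
#' betweenness averaged across participants.
#'
#' @param edge_bc_by_subject numeric matrix `subjects x edges`, columns
#'   named `"A|B"` (see [edge_bc_table()]).
#' @return list: `important` (named logical), `threshold`, `edge_mean`.
#' @export
edge_importance <- function(edge_bc_by_subject) {
  stopifnot(is.matrix(edge_bc_by_subject), nrow(edge_bc_by_subject) >= 2)
  edge_mean <- colMeans(edge_bc_by_subject)
  r <- one_sd_rule(edge_mean)
  imp <- r$flag
  names(imp) <- colnames(edge_bc_by_subject)
  list(important = imp, threshold = r$threshold, edge_mean = edge_mean)
}

#' Flatten an edge-betweenness matrix to a named vector
#'
#' @param eb symmetric matrix from [edge_betweenness_bc()].
#' @return named vector over the upper triangle, names `"A|B"`.
#' @export
edge_bc_table <- function(eb) {
  n <- nrow(eb)
  labels <- rownames(eb)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  ut <- which(upper.tri(eb), arr.ind = TRUE)
  v <- eb[ut]
  names(v) <- paste(labels[ut[, 1]], labels[ut[, 2]], sep = "|")
  v
}
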