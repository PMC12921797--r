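#' Kruskal-Wallis comparison of groups
#'
#' Thin wrapper around `stats::kruskal.test` (rank-based H statistic with
#' tie correction, chi-squared approximation with groups - 1 degrees of
#' freedom), with the degenerate all-tied case defined as H = 0, p = 1.
#'
#' @param samples_by_group list of numeric vectors, one per group.
#' @return list with `chi2`, `p` and `df`.
#' @export
kruskal_wallis <- function(samples_by_group) {
  if (!is.list(samples_by_group) || length(samples_by_group) < 2)
    stop("need at least 2 groups")
  if (any(lengths(samples_by_group) == 0)) stop("empty group")
  vals <- unlist(samples_by_group)
  df <- length(samples_by_group) - 1
  if (length(unique(vals)) == 1)
    return(list(chi2 = 0, p = 1, df = df))
  kt <- stats::kruskal.test(samples_by_group)
  list(chi2 = unname(kt$statistic), p = kt$p.value, df = df)
}

#' Global permutation test on a difference of group means
#'
#' Two-sided label-permutation test with statistic `mean(x) - mean(y)`.
#' The Monte-Carlo p-value uses the add-one estimator
#' `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)`, which is valid (never 0)
#' and exact on average. With `exact = TRUE` all label assignments are
#' enumerated instead and the p-value is the exact proportion.
#'
#' @param x,y numeric vectors (total length >= 4).
#' @param n_perm number of random permutations (1000 by default).
#' @param seed integer seed.
#' @param exact enumerate all `choose(n, n_x)` splits.
#' @return list: `p`, `statistic`, `n_perm` (or number of splits).
#' @export
permutation_test_global <- function(x, y, n_perm = 1000, seed = NULL,
                                    exact = FALSE) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n < 4) stop("need at least 4 observations in total")
  if (!exact && n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  v <- c(x, y)
  tobs <- mean(x) - mean(y)
  stat <- function(idx) mean(v[idx]) - mean(v[-idx])
  eps <- 1e-12
  if (exact) {
    splits <- utils::combn(n, n1)
    tp <- apply(splits, 2, stat)
    p <- mean(abs(tp) >= abs(tobs) - eps)
    return(list(p = p, statistic = tobs, n_perm = ncol(splits)))
  }
  if (!is.null(seed)) set.seed(seed)
  tp <- vapply(seq_len(n_perm),
               function(i) stat(sample.int(n, n1)), numeric(1))
  p <- (1 + sum(abs(tp) >= abs(tobs) - eps)) / (n_perm + 1)
  list(p = p, statistic = tobs, n_perm = n_perm)
}

#' Multiple-testing adjustment
#'
#' `method = "bonferroni"` controls the family-wise error rate over `m`
#' dependent measures by comparing each raw p-value to `alpha / m` (and
#' reporting `min(1, m * p)` as the adjusted p-value); with the package's
#' global measures `m = 3` (phi, dC, dL) the threshold is 0.05/3 ~ 0.0167,
#' and with the two node metrics `m = 2` it is 0.025. `method = "bh"` is
#' the Benjamini-Hochberg step-up procedure controlling the false
#' discovery rate at `q`.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha family-wise error rate (Bonferroni).
#' @param m number of comparisons (defaults to `length(p_values)`).
#' @param q target false discovery rate (BH).
#' @return list: `method`, `threshold` (Bonferroni per-test cutoff, or the
#'   realized BH cutoff), `p_adjusted`, `significant`.
#' @export
adjust_multiple <- function(p_values, method = c("bonferroni", "bh"),
                            alpha = 0.05, m = NULL, q = 0.05) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  if (method == "bonferroni") {
    if (is.null(m)) m <- length(p_values)
    if (m <= 0) stop("m must be positive")
    thr <- alpha / m
    padj <- pmin(1, m * p_values)
    sig <- p_values < thr
  } else {
    padj <- stats::p.adjust(p_values, method = "BH")
    sig <- padj <= q
    thr <- if (any(sig)) max(p_values[sig]) else 0
  }
  list(method = method, threshold = thr, p_adjusted = padj,
       significant = sig)
}

# Connected components among a set of supra-threshold nodes, split by the
# sign of their statistic (positive and negative clusters never merge).
supra_clusters <- function(z, supra, neighbors) {
  out <- list()
  todo <- which(supra)
  while (length(todo)) {
    seed_node <- todo[1]
    comp <- seed_node
    frontier <- seed_node
    sgn <- sign(z[seed_node])
    while (length(frontier)) {
      nb <- which(apply(neighbors[frontier, , drop = FALSE], 2, any))
      nb <- setdiff(intersect(nb, todo), comp)
      nb <- nb[sign(z[nb]) == sgn]
      comp <- c(comp, nb)
      frontier <- nb
    }
    out[[length(out) + 1]] <- sort(comp)
    todo <- setdiff(todo, comp)
  }
  out
}

#' Cluster-mass permutation test over the sensor graph
#'
#' Family-wise-error-controlled comparison of a per-node metric between two
#' groups. Each node gets a two-sided rank-sum statistic (tie-corrected
#' normal approximation of the Wilcoxon W); nodes with `p < cluster_alpha`
#' are grouped into sign-consistent clusters that are connected in the
#' sensor neighborhood graph; a cluster's mass is the summed |z| of its
#' members, and its corrected p-value comes from the permutation
#' distribution of the maximum cluster mass under group-label exchange.
#'
#' @param group_a,group_b numeric matrices `subjects x nodes`, same nodes.
#' @param neighbors symmetric logical sensor adjacency covering all nodes,
#'   see [montage_neighbors()].
#' @param cluster_alpha cluster-forming threshold (two-sided).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list: `clusters` (each with `members`, `mass`, `p_corrected`),
#'   `node_z`, `node_p`, `max_null` (the permutation distribution).
#' @export
cluster_mass_permutation <- function(group_a, group_b, neighbors,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = NULL) {
  stopifnot(is.matrix(group_a), is.matrix(group_b),
            ncol(group_a) == ncol(group_b))
  nn <- ncol(group_a)
  if (!is.matrix(neighbors) || nrow(neighbors) != nn ||
      !any(neighbors[upper.tri(neighbors)]))
    stop("neighbor graph must be a nonempty adjacency over all nodes")
  if (!is.null(seed)) set.seed(seed)
  n1 <- nrow(group_a); n2 <- nrow(group_b); N <- n1 + n2
  pooled <- rbind(group_a, group_b)
  R <- apply(pooled, 2, rank)
  mu <- n1 * (N + 1) / 2
  tiecorr <- apply(pooled, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  sdW <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecorr / (N * (N - 1))))
  sdW[sdW == 0] <- Inf                      # all-tied node: z = 0
  zcrit <- stats::qnorm(1 - cluster_alpha / 2)

  z_of <- function(idx) (colSums(R[idx, , drop = FALSE]) - mu) / sdW
  mass_of <- function(z) {
    supra <- abs(z) > zcrit
    if (!any(supra)) return(list(max = 0, clusters = list()))
    cl <- supra_clusters(z, supra, neighbors)
    masses <- vapply(cl, function(m) sum(abs(z[m])), numeric(1))
    list(max = max(masses), clusters = cl, masses = masses)
  }

  z_obs <- z_of(seq_len(n1))
  obs <- mass_of(z_obs)
  max_null <- vapply(seq_len(n_perm), function(i)
    mass_of(z_of(sample.int(N, n1)))$max, numeric(1))

  clusters <- list()
  if (length(obs$clusters)) {
    labels <- colnames(group_a)
    if (is.null(labels)) labels <- paste0("n", seq_len(nn))
    clusters <- lapply(seq_along(obs$clusters), function(i) {
      m <- obs$clusters[[i]]
      list(members = labels[m], mass = obs$masses[i],
           p_corrected = (1 + sum(max_null >= obs$masses[i] - 1e-12)) /
             (n_perm + 1))
    })
  }
  list(clusters = clusters, node_z = z_obs,
       node_p = 2 * stats::pnorm(-abs(z_obs)), max_null = max_null)
}

#' Inverse Efficiency Score
#'
#' `IES = mean reaction time of correct trials / proportion correct`, per
#' subject and condition (milliseconds). Lower is more efficient; the
#' accuracy denominator absorbs speed-accuracy trade-offs. Cells without a
#' single correct response have no defined IES and are flagged.
#'
#' @param records data.frame of behavioral records with columns
#'   `subject_id`, `condition`, `rt_ms`, `correct` (and optionally `group`).
#' @return data.frame: subject_id, condition (group if present), n_trials,
#'   accuracy, mean_rt_correct_ms, ies_ms, defined.
#' @export
compute_ies <- function(records) {
  stopifnot(all(c("subject_id", "condition", "rt_ms", "correct") %in%
                names(records)))
  if (any(records$rt_ms <= 0)) stop("reaction times must be positive")
  key <- paste(records$subject_id, records$condition, sep = "\r")
  rows <- lapply(split(records, key), function(d) {
    acc <- mean(d$correct)
    mrt <- if (any(d$correct)) mean(d$rt_ms[d$correct]) else NA_real_
    data.frame(subject_id = d$subject_id[1],
               group = if ("group" %in% names(d)) d$group[1] else NA_character_,
               condition = d$condition[1],
               n_trials = nrow(d), accuracy = acc,
               mean_rt_correct_ms = mrt,
               ies_ms = if (acc > 0) mrt / acc else NA_real_,
               defined = acc > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Robust regression of behavioral efficiency on network topology
#'
#' Huber M-estimation (tuning constant 1.345, iteratively reweighted via
#' `MASS::rlm`) of `ies ~ phi`. The slope's p-value uses the asymptotic
#' t statistic on n - 2 degrees of freedom; the coefficient of
#' determination is computed on the final robust weights, then adjusted as
#' `1 - (1 - R2)(n - 1)/(n - 2)`.
#'
#' @param ies per-subject inverse efficiency scores (ms).
#' @param phi per-subject small-world propensity values.
#' @param band,condition,group labels carried into the result.
#' @return data.frame (one row): band, condition, group, slope (ms per
#'   unit phi), intercept, p_slope, r2, adjusted_r2, n.
#' @export
robust_regress <- function(ies, phi, band = NA_character_,
                           condition = NA_character_,
                           group = NA_character_) {
  ok <- is.finite(ies) & is.finite(phi)
  ies <- ies[ok]; phi <- phi[ok]
  n <- length(ies)
  if (n < 5) stop("need at least 5 subjects")
  if (stats::var(phi) == 0) stop("zero variance in phi: slope undefined")
  ls <- stats::lm(ies ~ phi)
  if (suppressWarnings(summary(ls)$sigma) < 1e-8 * max(1, stats::sd(ies))) {
    # exact linear relationship: M-estimation degenerates, answer is exact
    co <- stats::coef(ls)
    return(data.frame(band = band, condition = condition, group = group,
                      slope = unname(co[2]), intercept = unname(co[1]),
                      p_slope = 0, r2 = 1, adjusted_r2 = 1, n = n,
                      stringsAsFactors = FALSE))
  }
  fit <- MASS::rlm(ies ~ phi, psi = MASS::psi.huber, k = 1.345,
                   maxit = 100)
  co <- summary(fit)$coefficients
  tval <- co["phi", "t value"]
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  w <- fit$w
  res <- stats::residuals(fit)
  ybar <- stats::weighted.mean(ies, w)
  r2 <- 1 - sum(w * res^2) / sum(w * (ies - ybar)^2)
  data.frame(band = band, condition = condition, group = group,
             slope = unname(co["phi", "Value"]),
             intercept = unname(co["(Intercept)", "Value"]),
             p_slope = p, r2 = r2,
             adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n,
             stringsAsFactors = FALSE)
}

#' Hemispheric comparison of a node metric
#'
#' Per subject, the median of the metric over left-hemisphere sensors and
#' over right-hemisphere sensors (midline excluded); the two sets of
#' per-subject medians are compared with a Wilcoxon rank-sum test.
#'
#' @param node_metric_by_subject matrix `subjects x nodes`, columns named
#'   with montage labels.
#' @param montage montage table with `label` and `hemisphere` columns.
#' @return list: `left`, `right` (per-subject medians), `median_diff`
#'   (left - right, of the medians), `p`, `statistic`.
#' @export
hemisphere_median_compare <- function(node_metric_by_subject,
                                      montage = standard_montage()) {
  labs <- colnames(node_metric_by_subject)
  stopifnot(!is.null(labs))
  hemi <- montage$hemisphere[match(labs, montage$label)]
  if (anyNA(hemi)) stop("labels not in montage: ",
                        paste(labs[is.na(hemi)], collapse = ", "))
  li <- which(hemi == "L"); ri <- which(hemi == "R")
  if (!length(li) || !length(ri)) stop("a hemisphere has no sensors")
  left <- apply(node_metric_by_subject[, li, drop = FALSE], 1, stats::median)
  right <- apply(node_metric_by_subject[, ri, drop = FALSE], 1, stats::median)
  wt <- suppressWarnings(stats::wilcox.test(left, right))
  list(left = left, right = right,
       median_diff = stats::median(left) - stats::median(right),
       p = wt$p.value, statistic = unname(wt$statistic))
}
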