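#' Assemble a pipeline run configuration
#'
#' Bundles every knob of the analysis into one serializable list: the
#' cohort (a synthetic-cohort configuration, or a directory of epoch sets
#' exported with [write_epochs_delim()]), the preprocessing thresholds, the
#' connectivity mode, null-model and permutation counts, and one master
#' seed from which every stochastic stage is derived. A config
#' round-trips unchanged through YAML.
#'
#' @param cohort synthetic-cohort config ([default_cohort_config()]).
#' @param connectivity_mode `"trials"` (default: graph metrics per
#'   single-trial wPLI matrix, then averaged per subject), `"average"`
#'   (across-trial mean of the single-trial matrices, one graph analysis
#'   per subject) or `"pooled"` (one wPLI estimate over the pooled
#'   within-trial samples — the estimator of choice when single trials are
#'   short relative to the band's coherence time).
#' @param subtract_evoked remove the cross-trial mean before phase
#'   extraction (induced-activity connectivity); see
#'   [subject_connectivity()].
#' @param n_random random null models per adjacency matrix.
#' @param n_perm permutations for group tests.
#' @param cluster_alpha cluster-forming threshold.
#' @param amp_limit_uv,snr_min trial-rejection thresholds.
#' @param alpha family-wise error rate; `fdr_q` FDR target.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = default_cohort_config(),
                       connectivity_mode = c("trials", "average", "pooled"),
                       subtract_evoked = FALSE,
                       n_random = 50, n_perm = 1000, cluster_alpha = 0.05,
                       amp_limit_uv = 200, snr_min = 1, alpha = 0.05,
                       fdr_q = 0.05, seed = 1) {
  structure(list(cohort = cohort,
                 connectivity_mode = match.arg(connectivity_mode),
                 subtract_evoked = subtract_evoked,
                 n_random = n_random, n_perm = n_perm,
                 cluster_alpha = cluster_alpha,
                 amp_limit_uv = amp_limit_uv, snr_min = snr_min,
                 alpha = alpha, fdr_q = fdr_q, seed = seed),
            class = "run_config")
}

se <- function(x) stats::sd(x) / sqrt(length(x))

subject_band_metrics <- function(band_epochs, mode, n_random,
                                 subtract_evoked = FALSE) {
  ws <- switch(mode,
               average = list(subject_connectivity(
                 band_epochs, "average", subtract_evoked = subtract_evoked)),
               pooled = list(subject_connectivity(
                 band_epochs, "pooled", subtract_evoked = subtract_evoked)),
               trials = {
                 arr <- subject_connectivity(
                   band_epochs, "trials", subtract_evoked = subtract_evoked)
                 lapply(seq_len(dim(arr)[3]), function(t) arr[, , t])
               })
  swps <- lapply(ws, small_world_propensity, n_random = n_random)
  nodes <- lapply(ws, node_strength_bc)
  ebs <- lapply(ws, function(w) edge_bc_table(edge_betweenness_bc(w)))
  avg <- function(f) mean(vapply(swps, function(s) s[[f]], numeric(1)))
  node_avg <- function(col)
    rowMeans(vapply(nodes, function(d) d[[col]], numeric(nrow(nodes[[1]]))))
  list(phi = avg("phi"), delta_c = avg("delta_c"), delta_l = avg("delta_l"),
       c_obs = avg("c_obs"), l_obs = avg("l_obs"),
       strength_norm = stats::setNames(node_avg("strength_norm"),
                                       nodes[[1]]$node),
       bc_norm = stats::setNames(node_avg("bc_norm"), nodes[[1]]$node),
       edge_bc = Reduce(`+`, ebs) / length(ebs))
}

#' Run the full network-analysis pipeline
#'
#' Orchestrates cohort generation (or ingest), trial rejection, epoch-count
#' balancing, band filtering, single-trial wPLI connectivity, small-world
#' propensity with lattice/random nulls, node/edge topology, group-level
#' permutation statistics with Bonferroni and Benjamini-Hochberg control,
#' cluster-mass tests on the sensor graph, hemisphere comparisons, and the
#' robust IES-efficiency regressions. The run is a pure function of
#' (config, seed): repeated runs reproduce every number exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all result tables, the
#'   report and a provenance log are written there.
#' @return A result bundle (class `swp_bundle`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  cohort <- simulate_cohort(config$cohort)
  bands <- cohort$truth$bands
  groups <- cohort$truth$groups
  conditions <- config$cohort$conditions
  montage <- standard_montage()[seq_len(config$cohort$n_channels), ]

  # --- trial rejection -----------------------------------------------------
  rej_rows <- list()
  kept <- cohort$epochs
  for (g in groups) for (s in names(kept[[g]])) for (cond in conditions) {
    r <- reject_trials(kept[[g]][[s]][[cond]],
                       amp_limit_uv = config$amp_limit_uv,
                       snr_min = config$snr_min)
    kept[[g]][[s]][[cond]] <- r$epochs
    rej_rows[[length(rej_rows) + 1]] <-
      data.frame(group = g, subject = s, condition = cond,
                 t(as.vector(r$report$counts)))
  }
  rejection <- do.call(rbind, rej_rows)
  names(rejection)[4:7] <- c("kept", "amplitude_rejected", "snr_rejected",
                             "incorrect_response")

  # --- balancing -----------------------------------------------------------
  kept <- balance_epoch_counts(kept, seed = config$seed + 1L)

  # --- connectivity + graph metrics ---------------------------------------
  set.seed(config$seed + 2L)
  met_rows <- list()
  node_store <- list()   # [[band]][[cond]][[group]]$strength / $bc / $edge
  for (g in groups) for (s in names(kept[[g]])) for (cond in conditions) {
    bd <- filter_bands(kept[[g]][[s]][[cond]], bands)
    for (b in bands$name) {
      m <- subject_band_metrics(bd[[b]], config$connectivity_mode,
                                config$n_random,
                                subtract_evoked = isTRUE(config$subtract_evoked))
      met_rows[[length(met_rows) + 1]] <-
        data.frame(group = g, subject = s, condition = cond, band = b,
                   phi = m$phi, delta_c = m$delta_c, delta_l = m$delta_l,
                   c_obs = m$c_obs, l_obs = m$l_obs)
      node_store[[b]][[cond]][[g]]$strength <-
        rbind(node_store[[b]][[cond]][[g]]$strength, m$strength_norm)
      node_store[[b]][[cond]][[g]]$bc <-
        rbind(node_store[[b]][[cond]][[g]]$bc, m$bc_norm)
      node_store[[b]][[cond]][[g]]$edge <-
        rbind(node_store[[b]][[cond]][[g]]$edge, m$edge_bc)
    }
  }
  metrics <- do.call(rbind, met_rows)

  # --- group statistics ----------------------------------------------------
  set.seed(config$seed + 3L)
  g1 <- groups[1]; g2 <- groups[2]
  glob_rows <- list()
  for (cond in conditions) for (b in bands$name) {
    sub <- metrics[metrics$condition == cond & metrics$band == b, ]
    for (meas in c("phi", "delta_c", "delta_l")) {
      x <- sub[[meas]][sub$group == g1]
      y <- sub[[meas]][sub$group == g2]
      pt <- permutation_test_global(x, y, n_perm = config$n_perm)
      glob_rows[[length(glob_rows) + 1]] <- data.frame(
        condition = cond, band = b, measure = meas,
        mean_1 = mean(x), se_1 = se(x), mean_2 = mean(y), se_2 = se(y),
        statistic = pt$statistic, p_perm = pt$p,
        stringsAsFactors = FALSE)
    }
  }
  global_tests <- do.call(rbind, glob_rows)
  names(global_tests)[4:7] <- c(paste0("mean_", g1), paste0("se_", g1),
                                paste0("mean_", g2), paste0("se_", g2))
  # Bonferroni over the three dependent global measures of one comparison
  global_tests$p_bonferroni <- pmin(1, 3 * global_tests$p_perm)
  global_tests$sig_bonferroni <- global_tests$p_perm < config$alpha / 3
  global_tests$sig_fdr <-
    adjust_multiple(global_tests$p_perm, "bh", q = config$fdr_q)$significant

  # hubs, edges, cluster tests, hemisphere comparison
  neighbors <- montage_neighbors(montage)
  hub_rows <- list(); clus_rows <- list(); hemi_rows <- list()
  edge_rows <- list()
  for (cond in conditions) for (b in bands$name) {
    st <- node_store[[b]][[cond]]
    for (g in groups) for (metric in c("strength", "bc")) {
      h <- detect_hubs(st[[g]][[metric]])
      hub_rows[[length(hub_rows) + 1]] <- data.frame(
        condition = cond, band = b, group = g, metric = metric,
        node = names(h$hub), node_mean = unname(h$node_mean),
        threshold = h$threshold, hub = unname(h$hub),
        stringsAsFactors = FALSE)
    }
    for (g in groups) {
      ei <- edge_importance(st[[g]]$edge)
      imp <- which(ei$important)
      if (length(imp))
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          condition = cond, band = b, group = g,
          edge = names(ei$important)[imp],
          edge_mean = unname(ei$edge_mean[imp]),
          threshold = ei$threshold, stringsAsFactors = FALSE)
    }
    for (metric in c("strength", "bc")) {
      cm <- cluster_mass_permutation(st[[g1]][[metric]], st[[g2]][[metric]],
                                     neighbors,
                                     cluster_alpha = config$cluster_alpha,
                                     n_perm = config$n_perm)
      for (cl in cm$clusters)
        clus_rows[[length(clus_rows) + 1]] <- data.frame(
          condition = cond, band = b, metric = metric,
          members = paste(cl$members, collapse = ","),
          mass = cl$mass, p_corrected = cl$p_corrected,
          sig = cl$p_corrected < config$alpha / 2,
          stringsAsFactors = FALSE)
    }
    for (g in groups) {
      hm <- hemisphere_median_compare(st[[g]]$strength, montage)
      hemi_rows[[length(hemi_rows) + 1]] <- data.frame(
        condition = cond, band = b, group = g, metric = "strength",
        median_left = stats::median(hm$left),
        median_right = stats::median(hm$right),
        median_diff = hm$median_diff, p = hm$p, stringsAsFactors = FALSE)
    }
  }
  hubs <- do.call(rbind, hub_rows)
  clusters <- if (length(clus_rows)) do.call(rbind, clus_rows) else
    data.frame(condition = character(), band = character(),
               metric = character(), members = character(),
               mass = numeric(), p_corrected = numeric(), sig = logical())
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
  hemisphere <- do.call(rbind, hemi_rows)

  # --- behavior ------------------------------------------------------------
  ies <- compute_ies(cohort$behavior)
  beh_rows <- list()
  for (cond in conditions) {
    sub <- ies[ies$condition == cond, ]
    for (meas in c("mean_rt_correct_ms", "accuracy")) {
      kw <- kruskal_wallis(split(sub[[meas]], sub$group))
      beh_rows[[length(beh_rows) + 1]] <- data.frame(
        condition = cond, measure = meas, chi2 = kw$chi2, p = kw$p,
        stringsAsFactors = FALSE)
    }
  }
  behavior_tests <- do.call(rbind, beh_rows)

  eff_rows <- list()
  for (cond in conditions) for (b in bands$name) for (g in groups) {
    sub <- metrics[metrics$condition == cond & metrics$band == b &
                     metrics$group == g, ]
    isub <- ies[ies$condition == cond & ies$group == g, ]
    phi <- sub$phi[match(isub$subject_id, sub$subject)]
    if (sum(is.finite(phi) & is.finite(isub$ies_ms)) >= 5 &&
        stats::var(phi, na.rm = TRUE) > 0)
      eff_rows[[length(eff_rows) + 1]] <-
        robust_regress(isub$ies_ms, phi, band = b, condition = cond,
                       group = g)
  }
  efficiency <- do.call(rbind, eff_rows)

  bundle <- structure(
    list(config = config, bands = bands, groups = groups,
         montage = montage, metrics = metrics, global_tests = global_tests,
         hubs = hubs, edges = edges, clusters = clusters,
         hemisphere = hemisphere, ies = ies,
         behavior_tests = behavior_tests, efficiency = efficiency,
         rejection = rejection, phi_true = cohort$phi_true,
         truth = cohort$truth,
         provenance = list(seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("swpnet")),
                           n_random = config$n_random,
                           n_perm = config$n_perm,
                           connectivity_mode = config$connectivity_mode,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs")))),
    class = "swp_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write all result tables of a pipeline run
#'
#' Emits tidy TSVs (global measures, per-subject metrics, hubs, important
#' edges, clusters, hemisphere comparisons, IES, efficiency fits, trial
#' rejection), a JSON summary in the layout of the group-comparison
#' tables, the human-readable report, and a provenance log.
#'
#' @param bundle an `swp_bundle`. @param out_dir output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) signif(x, 10))
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(bundle$global_tests, "global_measures.tsv")
  wt(bundle$metrics, "subject_metrics.tsv")
  wt(bundle$hubs, "hubs.tsv")
  if (!is.null(bundle$edges)) wt(bundle$edges, "important_edges.tsv")
  wt(bundle$clusters, "clusters.tsv")
  wt(bundle$hemisphere, "hemisphere.tsv")
  wt(bundle$ies, "ies.tsv")
  wt(bundle$behavior_tests, "behavior_tests.tsv")
  wt(bundle$efficiency, "efficiency_fits.tsv")
  wt(bundle$rejection, "rejection.tsv")
  jsonlite::write_json(
    list(global_measures = bundle$global_tests,
         behavior = bundle$behavior_tests,
         provenance = bundle$provenance),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(write_report(bundle), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a human-readable summary of a pipeline run
#'
#' Group means with standard errors, permutation p-values and correction
#' flags per band and measure, hub lists per band and metric, significant
#' clusters, and the efficiency regressions.
#'
#' @param bundle an `swp_bundle`.
#' @return character vector of report lines (also printable via `cat`).
#' @export
write_report <- function(bundle) {
  g1 <- bundle$groups[1]; g2 <- bundle$groups[2]
  num <- function(x) formatC(x, digits = 4, format = "f")
  out <- c("==== Small-world propensity network analysis ====", "")
  for (cond in unique(bundle$global_tests$condition)) {
    out <- c(out, sprintf("-- Global measures, condition: %s --", cond),
             sprintf("%-8s %-8s %22s %22s %8s %6s %4s", "band", "measure",
                     g1, g2, "p_perm", "bonf", "fdr"))
    gt <- bundle$global_tests[bundle$global_tests$condition == cond, ]
    for (i in seq_len(nrow(gt))) {
      r <- gt[i, ]
      out <- c(out, sprintf(
        "%-8s %-8s %10s +/- %-8s %10s +/- %-8s %8s %6s %4s",
        r$band, r$measure,
        num(r[[paste0("mean_", g1)]]), num(r[[paste0("se_", g1)]]),
        num(r[[paste0("mean_", g2)]]), num(r[[paste0("se_", g2)]]),
        num(r$p_perm), ifelse(r$sig_bonferroni, "*", ""),
        ifelse(r$sig_fdr, "*", "")))
    }
    out <- c(out, "")
  }
  out <- c(out, "-- Hubs (one-SD rule on group-averaged normalized metrics) --")
  hb <- bundle$hubs
  for (cond in unique(hb$condition)) for (b in unique(hb$band))
    for (g in unique(hb$group)) for (metric in unique(hb$metric)) {
      sel <- hb[hb$condition == cond & hb$band == b & hb$group == g &
                  hb$metric == metric & hb$hub, ]
      out <- c(out, sprintf("%s / %s / %s / %s: %s", cond, b, g, metric,
                            if (nrow(sel)) paste(sel$node, collapse = " ")
                            else "no hubs"))
    }
  out <- c(out, "", "-- Cluster-mass tests --")
  if (nrow(bundle$clusters)) {
    for (i in seq_len(nrow(bundle$clusters))) {
      r <- bundle$clusters[i, ]
      out <- c(out, sprintf("%s / %s / %s: {%s} mass=%s p=%s%s",
                            r$condition, r$band, r$metric, r$members,
                            num(r$mass), num(r$p_corrected),
                            ifelse(r$sig, " *", "")))
    }
  } else out <- c(out, "no suprathreshold clusters")
  out <- c(out, "", "-- Efficiency regressions (IES ~ phi) --")
  if (NROW(bundle$efficiency)) {
    for (i in seq_len(nrow(bundle$efficiency))) {
      r <- bundle$efficiency[i, ]
      out <- c(out, sprintf(
        "%s / %s / %s: slope=%s  adjR2=%s  p=%s", r$condition, r$band,
        r$group, num(r$slope), num(r$adjusted_r2), num(r$p_slope)))
    }
  } else out <- c(out, "not enough subjects for regression")
  out
}

#' @export
print.swp_bundle <- function(x, ...) {
  cat(write_report(x), sep = "\n")
  invisible(x)
}
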