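#' Ground-truth coupling network for the cohort generator
#'
#' Builds a Watts-Strogatz-style substrate: a ring lattice where every node
#' is joined to its `neighbors_k` nearest neighbours, each edge rewired with
#' probability `rewiring_p`. Edge weights (coupling strengths) are drawn
#' uniform(0.5, 1) times `weight_scale`; every edge also carries a fixed
#' phase lag drawn uniformly from +/-[pi/8, 3*pi/8] so that no true
#' connection is ever at zero or pi lag, where a phase-lag-based estimator
#' is blind by construction.
#'
#' Rewiring probability is the control knob for planted clustering
#' differences: low `rewiring_p` keeps the lattice's dense triangles, high
#' `rewiring_p` destroys them.
#'
#' @param n_nodes number of nodes (channels).
#' @param neighbors_k even lattice degree, `2 <= neighbors_k < n_nodes`.
#' @param rewiring_p per-edge rewiring probability in \[0, 1\].
#' @param weight_scale multiplier on the uniform(0.5, 1) weights.
#' @param seed integer seed; the draw is reproducible under it.
#' @return An object of class `ground_truth_network`: list with `n_nodes`,
#'   `adjacency` (symmetric, zero diagonal, nonnegative), `lag`
#'   (antisymmetric, radians) and `topology_params`.
#' @export
make_ground_truth_network <- function(n_nodes, neighbors_k, rewiring_p,
                                      weight_scale = 1, seed = NULL) {
  if (neighbors_k %% 2 != 0 || neighbors_k < 2 || n_nodes <= neighbors_k)
    stop("need n_nodes > neighbors_k >= 2 with neighbors_k even")
  if (rewiring_p < 0 || rewiring_p > 1) stop("rewiring_p must be in [0,1]")
  if (weight_scale <= 0) stop("weight_scale must be positive")
  if (!is.null(seed)) set.seed(seed)

  n <- n_nodes
  adj <- matrix(0, n, n)
  # ring lattice: node i connects to i +/- 1..k/2 (mod n)
  for (d in seq_len(neighbors_k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  # Watts-Strogatz rewiring: move the far endpoint of each lattice edge to a
  # uniformly chosen non-neighbour with probability rewiring_p
  for (d in seq_len(neighbors_k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      if (adj[i, j] == 0) next          # already rewired away
      if (stats::runif(1) < rewiring_p) {
        candidates <- which(adj[i, ] == 0 & seq_len(n) != i)
        if (length(candidates) == 0) next
        jj <- candidates[sample.int(length(candidates), 1)]
        adj[i, j] <- adj[j, i] <- 0
        adj[i, jj] <- adj[jj, i] <- 1
      }
    }
  }

  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  w <- stats::runif(nrow(edges), 0.5, 1) * weight_scale
  lag_mag <- stats::runif(nrow(edges), pi / 8, 3 * pi / 8)
  lag_sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
  W <- matrix(0, n, n)
  L <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    W[i, j] <- W[j, i] <- w[e]
    L[i, j] <- lag_sign[e] * lag_mag[e]
    L[j, i] <- -L[i, j]
  }
  structure(
    list(n_nodes = n, adjacency = W, lag = L,
         topology_params = list(neighbors_k = neighbors_k,
                                rewiring_p = rewiring_p,
                                weight_scale = weight_scale)),
    class = "ground_truth_network")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme, batch-vectorized);
# used for the trial-to-trial jitter on coupling lags.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(8L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[ok]; u3 <- u3[ok]
    out <- c(out, sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))))
  }
  out[seq_len(n)]
}

#' Simulate band-limited phase-coupled oscillator epochs
#'
#' The generative model behind the synthetic cohorts. Per band, every
#' channel carries a narrowband oscillator whose phase follows the band's
#' centre frequency plus Ornstein-Uhlenbeck drift (so uncoupled channels
#' decorrelate within a trial). A coupled pair additionally shares signal:
#' channel i receives channel j's oscillator phase-shifted by the edge's
#' fixed lag, with per-trial von Mises jitter whose concentration grows
#' with coupling strength, and with mixing gain proportional to the
#' coupling weight. Gaussian sensor noise is added, and a configurable
#' fraction of trials receives a high-amplitude (~+/-400 microvolt)
#' transient to exercise amplitude-based rejection.
#'
#' @param network a `ground_truth_network` (one per band, recycled if a
#'   single network is given).
#' @param bands band table as in [default_bands()]; one oscillator per band.
#' @param n_trials number of epochs to generate.
#' @param fs sampling rate (Hz). @param epoch_ms epoch length (ms).
#' @param amp_uv clean signal budget for the full seven-band set; each
#'   band's oscillator is scaled to `amp_uv / 7` no matter how many bands
#'   are simulated, so a band subset keeps per-band realism. At defaults,
#'   full-set trials sit near +/-50 microvolts, keeping the +/-200
#'   microvolt rejection rule meaningful.
#' @param evoked_uv peak amplitude of the stimulus-locked (evoked) response
#'   added identically to every trial: a damped 5 Hz oscillation starting
#'   at onset, with a fixed per-channel gain. It gives the epochs a
#'   realistic cross-trial mean (so the evoked-SNR rejection rule has
#'   something to measure) and, being common and instantaneous across
#'   channels, is invisible to a zero-lag-discarding connectivity measure.
#' @param noise_sd_uv additive Gaussian sensor noise sd.
#' @param artifact_rate per-trial probability of an injected transient.
#' @param coupling_gain mixing gain multiplying the coupling weights.
#' @param lag_jitter_kappa von Mises concentration per unit coupling weight.
#' @param drift_rate,drift_sd OU phase-drift parameters (1/s, rad/sqrt(s)).
#' @param mixing optional instantaneous symmetric leakage in \[0,1): each
#'   sample is mixed with the channel average, `x <- (1-mixing)*x +
#'   mixing*mean(x)`; zero-lag by construction, used to probe
#'   volume-conduction insensitivity.
#' @param seed integer seed.
#' @param ... metadata (`subject`, `group`, `condition`) for the epoch set.
#' @return An [epoch_set()] of `n_trials x n_nodes x samples` microvolt data.
#' @export
simulate_oscillator_epochs <- function(network, bands = default_bands(),
                                       n_trials, fs = 250, epoch_ms = 800,
                                       amp_uv = 45, evoked_uv = 15,
                                       noise_sd_uv = 5,
                                       artifact_rate = 0,
                                       coupling_gain = 0.8,
                                       lag_jitter_kappa = 8,
                                       drift_rate = 8, drift_sd = 6,
                                       mixing = 0, seed = NULL, ...) {
  if (nrow(bands) == 0) stop("empty band list")
  validate_bands(bands, fs)
  nsamp <- round(epoch_ms * fs / 1000)
  if (nsamp < 100) stop("fs and epoch_ms imply fewer than 100 samples")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(network, "ground_truth_network"))
    network <- rep(list(network), nrow(bands))
  if (length(network) != nrow(bands))
    stop("need one network per band (or a single network)")

  nch <- network[[1]]$n_nodes
  dt <- 1 / fs
  amp_band <- amp_uv / 7      # per-band scale fixed by the canonical set
  dat <- array(0, c(n_trials, nch, nsamp))

  # stimulus-locked evoked response, identical across trials: damped 5 Hz
  # oscillation with a per-channel gain (the only cross-trial-deterministic
  # signal component, hence what the evoked-SNR criterion measures)
  tgrid <- (0:(nsamp - 1)) * dt
  erp_shape <- exp(-tgrid / 0.25) * sin(2 * pi * 5 * tgrid)
  erp_gain <- stats::runif(nch, 0.7, 1.3) * evoked_uv
  erp <- outer(erp_gain, erp_shape)

  # all trials of a band are simulated as one stacked (channel, trial) x
  # sample matrix so the OU recursion runs once per band, not per trial
  nrow_all <- nch * n_trials
  X <- matrix(0, nrow_all, nsamp)
  for (b in seq_len(nrow(bands))) {
    net <- network[[b]]
    f0 <- (bands$low_hz[b] + bands$high_hz[b]) / 2
    # AR(1) phase drift run as one recursive filter over all series: the
    # stationary draw seeds row 1, innovations fill the rest
    psi0 <- stats::rnorm(nrow_all, 0, drift_sd / sqrt(2 * drift_rate))
    innov <- matrix(stats::rnorm(nrow_all * (nsamp - 1), 0,
                                 drift_sd * sqrt(dt)), nsamp - 1, nrow_all)
    psi <- stats::filter(rbind(psi0, innov), filter = 1 - drift_rate * dt,
                         method = "recursive")
    psi <- t(matrix(as.numeric(psi), nsamp, nrow_all))
    theta <- matrix((0:(nsamp - 1)) * dt * 2 * pi * f0, nrow_all, nsamp,
                    byrow = TRUE) + psi + stats::runif(nrow_all, 0, 2 * pi)
    Cb <- cos(theta); Sb <- sin(theta)
    mix <- Cb
    gain_tot <- rep(1, nch)
    edges <- which(upper.tri(net$adjacency) & net$adjacency > 0,
                   arr.ind = TRUE)
    rows_of <- function(ch) ch + nch * (seq_len(n_trials) - 1)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      w <- net$adjacency[i, j]
      g <- coupling_gain * w
      # cos(theta - phase) expanded so the trig runs once per band, with
      # phase = lag - per-trial von Mises jitter
      ph_i <- net$lag[i, j] - rvonmises(n_trials, lag_jitter_kappa * w)
      ph_j <- net$lag[j, i] - rvonmises(n_trials, lag_jitter_kappa * w)
      ri <- rows_of(i); rj <- rows_of(j)
      mix[ri, ] <- mix[ri, ] + g * (Cb[rj, ] * cos(ph_i) + Sb[rj, ] * sin(ph_i))
      mix[rj, ] <- mix[rj, ] + g * (Cb[ri, ] * cos(ph_j) + Sb[ri, ] * sin(ph_j))
      gain_tot[i] <- gain_tot[i] + g
      gain_tot[j] <- gain_tot[j] + g
    }
    X <- X + amp_band * mix / gain_tot            # gain recycles per channel
  }
  for (trial in seq_len(n_trials)) {
    x <- X[(trial - 1) * nch + seq_len(nch), , drop = FALSE]
    if (mixing > 0)
      x <- (1 - mixing) * x + mixing * matrix(colMeans(x), nch, nsamp,
                                              byrow = TRUE)
    x <- x + erp + matrix(stats::rnorm(nch * nsamp, 0, noise_sd_uv), nch, nsamp)
    if (artifact_rate > 0 && stats::runif(1) < artifact_rate) {
      ch <- sample.int(nch, 1)
      at <- sample.int(nsamp - 25, 1)
      bump <- 400 * sign(stats::runif(1) - 0.5) *
        (1 - cos(2 * pi * (0:24) / 24)) / 2      # 100 ms raised cosine
      x[ch, at:(at + 24)] <- x[ch, at:(at + 24)] + bump
    }
    dat[trial, , ] <- x
  }
  epoch_set(dat, fs = fs, channels = paste0("ch", seq_len(nch)),
            window_ms = epoch_ms, ...)
}

#' Simulate until a target number of clean epochs is reached
#'
#' Mirrors the acquisition protocol for hard-to-record cohorts: batches of
#' trials are simulated and passed through artifact/SNR rejection, and
#' recording continues (up to `max_batches`) until `n_clean` clean epochs
#' are available. Subjects whose signals sit near the rejection threshold
#' therefore end up with the same usable trial count as everyone else,
#' as they would after additional recording sessions.
#'
#' @inheritParams simulate_oscillator_epochs
#' @param n_clean target number of clean epochs.
#' @param batch trials simulated per batch; the default oversamples by 40%
#'   so that typical rejection rates are absorbed in a single session.
#' @param max_batches stop (with an error) after this many batches.
#' @param amp_limit_uv,snr_min rejection thresholds, see [reject_trials()].
#' @return An [epoch_set()] with exactly `n_clean` trials.
#' @export
simulate_clean_epochs <- function(network, bands = default_bands(), n_clean,
                                  batch = ceiling(1.4 * n_clean),
                                  max_batches = 10,
                                  amp_limit_uv = 200, snr_min = 1,
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  kept <- NULL
  for (i in seq_len(max_batches)) {
    es <- simulate_oscillator_epochs(network, bands, n_trials = batch, ...)
    r <- tryCatch(reject_trials(es, amp_limit_uv = amp_limit_uv,
                                snr_min = snr_min)$epochs,
                  error = function(e) NULL)
    if (!is.null(r)) {
      if (is.null(kept)) kept <- r
      else {
        dat <- array(0, c(n_trials(kept) + n_trials(r), n_channels(r),
                          n_samples(r)))
        dat[seq_len(n_trials(kept)), , ] <- kept$data
        dat[n_trials(kept) + seq_len(n_trials(r)), , ] <- r$data
        kept$data <- dat
      }
    }
    if (!is.null(kept) && n_trials(kept) >= n_clean)
      return(subset_trials(kept, seq_len(n_clean)))
  }
  stop("could not collect ", n_clean, " clean epochs in ", max_batches,
       " batches")
}

#' Default synthetic-cohort configuration
#'
#' Encodes the study design the generator emulates: a control group of 20
#' and a dyslexia ("dd") group of 24 subjects, two auditory conditions
#' (word / pseudoword), 800 ms epochs at 250 Hz on the 40-channel montage,
#' clean-epoch counts of 32 +/- 5 (control) and 21 +/- 7 (dd) per subject
#' and condition, and 40 behavioral trials per condition. The planted group
#' difference is topological: control networks are rewired at p = 0.1 and
#' dd networks at p = 0.5, so the dd group has systematically lower
#' ground-truth clustering in every band. Behavior is planted with a
#' negative IES-vs-phi slope of -2000 ms per unit phi.
#'
#' @param ... named overrides merged into the default list.
#' @return A config list accepted by [simulate_cohort()].
#' @export
default_cohort_config <- function(...) {
  cfg <- list(
    n_subjects = c(control = 20, dd = 24),
    conditions = c("word", "pseudoword"),
    bands = default_bands()$name,
    fs = 250,
    epoch_ms = 800,
    epochs_per_subject = list(control = c(mean = 32, sd = 5),
                              dd = c(mean = 21, sd = 7)),
    network = list(neighbors_k = 4, weight_scale = 1,
                   rewiring_p = c(control = 0.1, dd = 0.5),
                   coupling_gain = 0.8, lag_jitter_kappa = 8),
    amp_uv = 45, evoked_uv = 15, noise_sd_uv = 5, artifact_rate = 0.1,
    behavior = list(base_ies_ms = 2600, slope_ies_vs_phi = -2000,
                    rt_noise_sd_ms = 150,
                    accuracy_logit = c(intercept = -0.1, slope = 2),
                    n_trials = 40),
    n_channels = 40,
    phi_null_models = 20,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read / write a cohort configuration file
#'
#' Round-trips the config list of [default_cohort_config()] through YAML.
#'
#' @param path file path. @param config config list.
#' @return `read_cohort_config` returns the config list.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_cohort_config()
  base[names(cfg)] <- cfg
  base$n_subjects <- unlist(base$n_subjects)
  base$network$rewiring_p <- unlist(base$network$rewiring_p)
  base$behavior$accuracy_logit <- unlist(base$behavior$accuracy_logit)
  for (g in names(base$epochs_per_subject))
    base$epochs_per_subject[[g]] <- unlist(base$epochs_per_subject[[g]])
  base
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  # named atomic vectors become YAML maps (as.list, recursively) so their
  # names survive the round trip
  listify <- function(x) {
    if (is.list(x)) return(lapply(x, listify))
    if (!is.null(names(x)) && length(x) > 1) return(as.list(x))
    x
  }
  yaml::write_yaml(listify(config), path)
  invisible(path)
}

#' Draw the ground truth for a synthetic cohort
#'
#' Samples an independent ground-truth network per subject and band (same
#' topology parameters within a group), records the planted clustering
#' contrast, and carries the behavioral parameters. The result is the
#' "answer key" that recovery tests re-estimate from the simulated data.
#'
#' @param config cohort configuration, see [default_cohort_config()].
#' @return An object of class `cohort_truth`.
#' @export
make_cohort_truth <- function(config = default_cohort_config()) {
  set.seed(config$seed)
  bands <- default_bands(config$bands)
  groups <- names(config$n_subjects)
  networks <- list()
  for (g in groups) {
    p <- config$network$rewiring_p[[g]]
    networks[[g]] <- lapply(seq_len(config$n_subjects[[g]]), function(s) {
      nets <- lapply(seq_len(nrow(bands)), function(b)
        make_ground_truth_network(config$n_channels,
                                  config$network$neighbors_k, p,
                                  config$network$weight_scale))
      names(nets) <- bands$name
      nets
    })
    names(networks[[g]]) <- sprintf("%s%02d", g, seq_len(config$n_subjects[[g]]))
  }
  structure(
    list(config = config, bands = bands, groups = groups,
         networks = networks,
         planted_contrast = list(
           measure = "ground-truth clustering",
           rewiring_p = config$network$rewiring_p,
           expected_direction = "mean clustering higher in the low-rewiring group"),
         seed = config$seed),
    class = "cohort_truth")
}

#' Simulate all epoch sets for a cohort
#'
#' @param truth a `cohort_truth` from [make_cohort_truth()].
#' @param montage montage table; its first `n_channels` labels are used.
#' @return Nested list `epochs[[group]][[subject]][[condition]]`, each an
#'   [epoch_set()]. Bit-identical for identical truth (the seed lives in
#'   the truth object).
#' @export
simulate_cohort_epochs <- function(truth, montage = standard_montage()) {
  stopifnot(inherits(truth, "cohort_truth"))
  cfg <- truth$config
  bands <- truth$bands
  labels <- montage$label[seq_len(cfg$n_channels)]
  set.seed(truth$seed + 1L)
  out <- list()
  for (g in truth$groups) {
    out[[g]] <- list()
    eps <- cfg$epochs_per_subject[[g]]
    for (s in names(truth$networks[[g]])) {
      out[[g]][[s]] <- list()
      for (cond in cfg$conditions) {
        nt <- max(5L, round(stats::rnorm(1, eps[["mean"]], eps[["sd"]])))
        es <- simulate_oscillator_epochs(
          truth$networks[[g]][[s]], bands = bands, n_trials = nt,
          fs = cfg$fs, epoch_ms = cfg$epoch_ms, amp_uv = cfg$amp_uv,
          evoked_uv = cfg$evoked_uv, noise_sd_uv = cfg$noise_sd_uv,
          artifact_rate = cfg$artifact_rate,
          coupling_gain = cfg$network$coupling_gain,
          lag_jitter_kappa = cfg$network$lag_jitter_kappa,
          subject = s, group = g, condition = cond)
        es$channels <- labels
        out[[g]][[s]][[cond]] <- es
      }
    }
  }
  out
}

#' Simulate behavioral records tied to network efficiency
#'
#' Generates per-trial reaction times and correctness so that the expected
#' Inverse Efficiency Score of a subject is a linear function of that
#' subject's small-world propensity phi: `E[IES] = base + slope * phi`.
#' Accuracy follows a logistic link in phi; correct-trial reaction times
#' are lognormal around the subject mean chosen so that mean RT / accuracy
#' hits the target IES.
#'
#' @param phi_by_subject named numeric vector of phi values in \[0,1\].
#' @param behavior_params list with `base_ies_ms`, `slope_ies_vs_phi`,
#'   `rt_noise_sd_ms` and `accuracy_logit` (intercept, slope).
#' @param n_trials trials per subject.
#' @param seed integer seed.
#' @param condition,group optional labels stored on every record.
#' @return data.frame of `BehavioralRecord`s: subject_id, group, condition,
#'   rt_ms (> 0), correct.
#' @export
simulate_behavior <- function(phi_by_subject, behavior_params, n_trials,
                              seed = NULL, condition = NA_character_,
                              group = NA_character_) {
  stopifnot(all(phi_by_subject >= 0 & phi_by_subject <= 1))
  bp <- behavior_params
  if (!is.null(seed)) set.seed(seed)
  al <- bp$accuracy_logit
  recs <- lapply(names(phi_by_subject), function(s) {
    phi <- phi_by_subject[[s]]
    p <- stats::plogis(al[["intercept"]] + al[["slope"]] * phi)
    if (p <= 0 || p > 1 || is.na(p))
      stop("accuracy parameters imply accuracy outside (0, 1]")
    ies <- bp$base_ies_ms + bp$slope_ies_vs_phi * phi
    mu_rt <- ies * p
    if (mu_rt <= 0)
      stop("behavior parameters imply non-positive mean reaction time")
    if (bp$rt_noise_sd_ms <= 0) {
      rt <- rep(mu_rt, n_trials)
    } else {
      sdlog <- sqrt(log(1 + (bp$rt_noise_sd_ms / mu_rt)^2))
      rt <- stats::rlnorm(n_trials, log(mu_rt) - sdlog^2 / 2, sdlog)
    }
    data.frame(subject_id = s, group = group, condition = condition,
               rt_ms = rt,
               correct = stats::runif(n_trials) < p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Generate a complete synthetic cohort
#'
#' Draws the ground truth, simulates all epoch sets, computes each
#' subject's ground-truth small-world propensity (mean over bands) and
#' plants behavior on it. This is the one-call entry point the pipeline
#' consumes.
#'
#' @param config see [default_cohort_config()]; may also be a path to a
#'   YAML configuration file.
#' @return list with `truth`, `epochs`, `phi_true` (per group, subject) and
#'   `behavior` (data.frame over all groups and conditions).
#' @export
simulate_cohort <- function(config = default_cohort_config()) {
  if (is.character(config)) config <- read_cohort_config(config)
  truth <- make_cohort_truth(config)
  epochs <- simulate_cohort_epochs(truth)
  set.seed(truth$seed + 2L)
  phi_true <- lapply(truth$groups, function(g) {
    vapply(truth$networks[[g]], function(nets) {
      mean(vapply(nets, function(net) {
        small_world_propensity(net$adjacency,
                               n_random = config$phi_null_models)$phi
      }, numeric(1)))
    }, numeric(1))
  })
  names(phi_true) <- truth$groups
  set.seed(truth$seed + 3L)
  behavior <- do.call(rbind, lapply(truth$groups, function(g) {
    do.call(rbind, lapply(config$conditions, function(cond) {
      simulate_behavior(phi_true[[g]], config$behavior,
                        n_trials = config$behavior$n_trials,
                        condition = cond, group = g)
    }))
  }))
  rownames(behavior) <- NULL
  list(truth = truth, epochs = epochs, phi_true = phi_true,
       behavior = behavior)
}

#' Save the ground truth as JSON for recovery tests
#'
#' @param truth a `cohort_truth`. @param path output path.
#' @export
write_cohort_truth <- function(truth, path) {
  contrast <- truth$planted_contrast
  contrast$rewiring_p <- as.list(contrast$rewiring_p)  # keep names in JSON
  ser <- list(
    config = truth$config,
    planted_contrast = contrast,
    networks = lapply(truth$networks, function(g)
      lapply(g, function(s) lapply(s, function(net)
        list(adjacency = net$adjacency, lag = net$lag,
             topology_params = net$topology_params))))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
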