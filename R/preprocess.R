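# One-direction IIR (transposed direct form) on a samples x series matrix,
# zero initial conditions, columns filtered independently. The MA part is a
# causal convolution (zero-padded head), the AR part a recursive filter.
iir_filter_mat <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  Y <- stats::filter(Xp, filter = b, method = "convolution", sides = 1)
  Y <- Y[nb:nrow(Y), , drop = FALSE]
  if (length(a) > 1)
    Y <- stats::filter(Y, filter = -a[-1], method = "recursive")
  matrix(as.numeric(Y), nrow(X), ncol(X))
}

# forward-backward (zero-phase) application of an ARMA filter
filtfilt_mat <- function(flt, X) {
  Y <- iir_filter_mat(flt$b, flt$a, X)
  Y <- iir_filter_mat(flt$b, flt$a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE]
}

#' Zero-phase band decomposition of an epoch set
#'
#' Applies the preprocessing filter chain and splits the data into the
#' analysis bands. Every channel of every trial is first reflection-padded
#' by half an epoch on each side (to suppress filter edge transients on
#' short epochs), then broadband filtered (default 1-70 Hz) with a 50 Hz
#' band-stop notch, then band-pass filtered per band with a 4th-order
#' Butterworth applied forward and backward (`signal::filtfilt`), which
#' cancels the filter's phase response — essential ahead of any phase-based
#' connectivity estimate. The padded segment is re-cropped to the original
#' epoch window.
#'
#' @param epochs an [epoch_set()].
#' @param bands band table, see [default_bands()].
#' @param broadband length-2 numeric, the initial band-pass (Hz); `NULL`
#'   skips the broadband stage.
#' @param notch_hz line frequency to remove (Hz); `NULL` skips the notch.
#' @param order Butterworth design order.
#' @return Named list mapping band name to a band-limited `epoch_set`.
#' @export
filter_bands <- function(epochs, bands = default_bands(),
                         broadband = c(1, 70), notch_hz = 50, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  validate_bands(bands, fs)
  ns <- n_samples(epochs)
  if (ns < 3 * order) stop("epoch too short for the filter order")
  nyq <- fs / 2

  pad <- floor(ns / 2)
  bb <- if (!is.null(broadband))
    signal::butter(order, pmin(broadband, nyq * 0.99) / nyq, type = "pass")
  ntch <- if (!is.null(notch_hz))
    signal::butter(2, c(notch_hz - 2, notch_hz + 2) / nyq, type = "stop")
  bfs <- lapply(seq_len(nrow(bands)), function(b)
    signal::butter(order, c(bands$low_hz[b], bands$high_hz[b]) / nyq,
                   type = "pass"))

  nt <- n_trials(epochs); nc <- n_channels(epochs)
  # samples x (trial, channel) matrix with reflection padding, filtered as
  # one block: stats::filter runs column-wise over all series at once
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), ns, nt * nc)
  Xp <- rbind(X[pad:1, , drop = FALSE], X, X[ns:(ns - pad + 1), , drop = FALSE])
  if (!is.null(broadband)) Xp <- filtfilt_mat(bb, Xp)
  if (!is.null(notch_hz)) Xp <- filtfilt_mat(ntch, Xp)

  core <- (pad + 1):(pad + ns)
  out <- lapply(seq_len(nrow(bands)), function(b) {
    Yb <- filtfilt_mat(bfs[[b]], Xp)[core, , drop = FALSE]
    e <- epochs
    e$data <- aperm(array(Yb, c(ns, nt, nc)), c(2, 3, 1))
    e
  })
  names(out) <- bands$name
  out
}

#' Artifact, SNR and response-based trial rejection
#'
#' Applies the three rejection rules in a fixed order: (1) amplitude — a
#' trial is dropped if any sample on any channel exceeds
#' `+/-amp_limit_uv`; (2) signal-to-noise — on the amplitude-clean trials,
#' each sensor's noise in a trial is the standard deviation of the residual
#' after subtracting the across-trial mean signal, and the trial is dropped
#' if any sensor's `peak-to-peak(mean) / (2 * sd(residual))` falls below
#' `snr_min`; (3) behavioral — trials answered incorrectly are dropped.
#' Computing the SNR mean on amplitude-clean trials only keeps gross
#' artifacts from corrupting the reference signal.
#'
#' @param epochs an [epoch_set()] with at least 2 trials.
#' @param amp_limit_uv amplitude rejection threshold (microvolts).
#' @param snr_min minimum acceptable SNR; the SNR formula has no natural
#'   cut-off, so the default 1 demands signal at least as large as noise.
#' @param correct_flags optional logical vector (one per trial); `NULL`
#'   skips the behavioral rule.
#' @return list with `epochs` (kept trials, original order) and `report`, a
#'   `rejection_report`: per-trial status plus the per-trial x sensor SNR
#'   matrix for the amplitude-clean trials.
#' @export
reject_trials <- function(epochs, amp_limit_uv = 200, snr_min = 1,
                          correct_flags = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_trials(epochs)
  if (nt < 2) stop("need at least 2 trials (SNR uses a cross-trial mean)")
  if (!is.null(correct_flags) && length(correct_flags) != nt)
    stop("correct_flags length must match trial count")

  status <- rep("kept", nt)

  amp_bad <- apply(abs(epochs$data), 1, max) > amp_limit_uv
  status[amp_bad] <- "amplitude_rejected"

  clean <- which(!amp_bad)
  snr <- NULL
  if (length(clean) >= 2) {
    mean_sig <- apply(epochs$data[clean, , , drop = FALSE], c(2, 3), mean)
    p2p <- apply(mean_sig, 1, function(v) max(v) - min(v))
    snr <- matrix(NA_real_, nt, n_channels(epochs),
                  dimnames = list(NULL, epochs$channels))
    for (t in clean) {
      resid <- epochs$data[t, , ] - mean_sig
      noise <- apply(resid, 1, stats::sd)
      snr[t, ] <- ifelse(noise == 0, Inf, p2p / (2 * noise))
    }
    snr_bad <- clean[apply(snr[clean, , drop = FALSE] < snr_min, 1, any)]
    status[snr_bad] <- "snr_rejected"
  } else if (length(clean) > 0) {
    warning("fewer than 2 amplitude-clean trials; SNR stage skipped")
  }

  if (!is.null(correct_flags)) {
    wrong <- which(status == "kept" & !correct_flags)
    status[wrong] <- "incorrect_response"
  }

  keep <- which(status == "kept")
  if (length(keep) == 0) stop("all trials rejected")
  report <- structure(
    list(status = status,
         counts = table(factor(status, levels = c(
           "kept", "amplitude_rejected", "snr_rejected",
           "incorrect_response"))),
         snr = snr,
         amp_limit_uv = amp_limit_uv, snr_min = snr_min),
    class = "rejection_report")
  list(epochs = subset_trials(epochs, keep), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report>\n")
  print(x$counts)
  invisible(x)
}

#' Export a rejection report as TSV
#' @param report a `rejection_report`. @param path output path.
#' @export
write_rejection_report <- function(report, path) {
  utils::write.table(
    data.frame(trial = seq_along(report$status), status = report$status),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Equalize clean-epoch counts across groups
#'
#' Clean-epoch counts typically differ systematically between clinical
#' groups; to keep connectivity estimates statistically comparable, every
#' subject/condition cell is randomly subsampled without replacement down
#' to the minimum count found anywhere in the cohort. Kept trials stay in
#' their original order; labels are untouched. Deterministic under `seed`.
#'
#' @param groups nested list `group -> subject -> condition -> epoch_set`
#'   (or any nesting whose leaves are epoch sets).
#' @param seed integer seed.
#' @return The same structure with equal trial counts everywhere.
#' @export
balance_epoch_counts <- function(groups, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  leaves <- function(x) {
    if (inherits(x, "epoch_set")) return(list(x))
    do.call(c, lapply(x, leaves))
  }
  counts <- vapply(leaves(groups), n_trials, integer(1))
  if (any(counts < 1)) stop("every subject needs at least 1 kept epoch")
  target <- min(counts)
  prune <- function(x) {
    if (inherits(x, "epoch_set")) {
      if (n_trials(x) == target) return(x)
      return(subset_trials(x, sort(sample.int(n_trials(x), target))))
    }
    lapply(x, prune)
  }
  prune(groups)
}
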