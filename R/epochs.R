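#' Construct an epoch set
#'
#' The central data container: a stack of equal-length, onset-locked trials
#' for one subject and condition. Data are stored as a 3-D numeric array
#' `trials x channels x samples` in microvolts.
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (montage order).
#' @param subject,group,condition scalar labels attached to every trial.
#' @param window_ms epoch length in milliseconds (defaults to
#'   `1000 * samples / fs`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels, subject = NA_character_,
                      group = NA_character_, condition = NA_character_,
                      window_ms = NULL) {
  if (length(dim(data)) != 3)
    stop("data must be a trials x channels x samples array")
  if (dim(data)[2] != length(channels))
    stop("channel dimension (", dim(data)[2], ") does not match ",
         length(channels), " labels")
  stopifnot(is.numeric(fs), fs > 0)
  if (is.null(window_ms)) window_ms <- 1000 * dim(data)[3] / fs
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         subject = subject, group = group, condition = condition,
         window_ms = window_ms),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  subject=%s group=%s condition=%s window=%g ms\n",
              x$subject, x$group, x$condition, x$window_ms))
  invisible(x)
}

n_trials   <- function(epochs) dim(epochs$data)[1]
n_channels <- function(epochs) dim(epochs$data)[2]
n_samples  <- function(epochs) dim(epochs$data)[3]

# Replace the trial dimension, keeping metadata.
subset_trials <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs
}

#' Cut onset-locked epochs from a continuous recording
#'
#' @param continuous numeric matrix `channels x samples`.
#' @param onsets 0-based sample indices of stimulus onsets.
#' @param window_ms epoch length (default 800 ms).
#' @param fs sampling rate (default 250 Hz).
#' @param channels optional channel labels (defaults to rownames).
#' @param ... metadata passed on to [epoch_set()].
#' @return An `epoch_set` with `round(window_ms * fs / 1000)` samples per
#'   trial, each trial the half-open slice `[onset, onset + n)`. Onsets
#'   whose window overruns the recording are skipped with a warning and
#'   recorded in the `skipped_onsets` attribute.
#' @export
segment_epochs <- function(continuous, onsets, window_ms = 800, fs = 250,
                           channels = rownames(continuous), ...) {
  stopifnot(is.matrix(continuous), is.numeric(onsets))
  nsamp <- round(window_ms * fs / 1000)
  total <- ncol(continuous)
  ok <- onsets >= 0 & (onsets + nsamp) <= total
  if (any(!ok))
    warning(sum(!ok), " onset(s) overrun the recording and were skipped")
  kept <- onsets[ok]
  if (length(kept) == 0) stop("no onset leaves a complete epoch")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(continuous)))
  dat <- array(NA_real_, c(length(kept), nrow(continuous), nsamp))
  for (t in seq_along(kept)) {
    dat[t, , ] <- continuous[, (kept[t] + 1):(kept[t] + nsamp), drop = FALSE]
  }
  out <- epoch_set(dat, fs = fs, channels = channels, window_ms = window_ms, ...)
  attr(out, "skipped_onsets") <- onsets[!ok]
  out
}
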