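#' Read / write a continuous recording as delimited text
#'
#' The plain-text exchange format: one column per channel with a header row
#' of channel labels, one row per sample (microvolts). Returned transposed
#' to the package's `channels x samples` orientation.
#'
#' @param path file path. @param sep field separator (tab).
#' @return `read_delimited_recording`: numeric matrix `channels x samples`
#'   with channel labels as rownames.
#' @export
read_delimited_recording <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE)
  m <- t(as.matrix(d))
  storage.mode(m) <- "double"
  m
}

#' @rdname read_delimited_recording
#' @param continuous numeric matrix `channels x samples`, rownames = labels.
#' @export
write_delimited_recording <- function(continuous, path, sep = "\t") {
  stopifnot(is.matrix(continuous), !is.null(rownames(continuous)))
  d <- as.data.frame(t(continuous))
  names(d) <- rownames(continuous)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an epoch set as per-trial delimited matrices
#'
#' Writes `trial_###.tsv` files (samples x channels, labelled header) plus
#' an `index.tsv` carrying the metadata, into `dir`.
#'
#' @param epochs an [epoch_set()]. @param dir output directory.
#' @export
write_epochs_delim <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_trials(epochs)
  files <- sprintf("trial_%03d.tsv", seq_len(nt))
  for (t in seq_len(nt)) {
    m <- matrix(epochs$data[t, , ], n_channels(epochs))
    rownames(m) <- epochs$channels
    write_delimited_recording(m, file.path(dir, files[t]))
  }
  utils::write.table(
    data.frame(trial = seq_len(nt), file = files, fs = epochs$fs,
               subject = epochs$subject, group = epochs$group,
               condition = epochs$condition),
    file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs_delim()]
#' @param dir directory containing `index.tsv` and trial files.
#' @return An [epoch_set()].
#' @export
read_epochs_delim <- function(dir) {
  idx <- utils::read.table(file.path(dir, "index.tsv"), header = TRUE,
                           sep = "\t")
  mats <- lapply(file.path(dir, idx$file), read_delimited_recording)
  dat <- array(0, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (t in seq_along(mats)) dat[t, , ] <- mats[[t]]
  epoch_set(dat, fs = idx$fs[1], channels = rownames(mats[[1]]),
            subject = as.character(idx$subject[1]),
            group = as.character(idx$group[1]),
            condition = as.character(idx$condition[1]))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Minimal EDF writer for continuous recordings
#'
#' Writes a single-record European Data Format file: 16-bit samples scaled
#' to the per-channel physical range. Sufficient for exchanging simulated
#' continuous data with standard EDF tooling; annotations and multi-record
#' layouts are out of scope.
#'
#' @param continuous numeric matrix `channels x samples` (microvolts),
#'   rownames used as signal labels.
#' @param path output path. @param fs sampling rate in Hz.
#' @export
write_edf <- function(continuous, path, fs) {
  stopifnot(is.matrix(continuous), !is.null(rownames(continuous)))
  nc <- nrow(continuous); ns <- ncol(continuous)
  pmin_ <- apply(continuous, 1, min); pmax_ <- apply(continuous, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(paste0(vapply(x, pad_ascii, "", w),
                                        collapse = ""), con, eos = NULL)
  wr("0", 8); wr("swpnet synthetic", 80); wr("swpnet recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + nc), 8); wr("", 44); wr(1, 8)
  wr(format(ns / fs, digits = 8), 8); wr(nc, 4)
  wr(rownames(continuous), 16)
  wr(rep("", nc), 80); wr(rep("uV", nc), 8)
  wr(format(pmin_, digits = 7), 8); wr(format(pmax_, digits = 7), 8)
  wr(rep(dmin, nc), 8); wr(rep(dmax, nc), 8)
  wr(rep("", nc), 80); wr(rep(ns, nc), 8); wr(rep("", nc), 32)
  for (ch in seq_len(nc)) {
    dig <- round((continuous[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads files produced by [write_edf()] and other plain (non-annotated)
#' EDF recordings, concatenating data records per signal and applying the
#' digital-to-physical scaling. Signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return list: `data` (`channels x samples` matrix, labelled), `fs`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header bytes (implied by ns)
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)             # transducer
  for (i in seq_len(nc)) rd(8)              # dimension
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)             # prefilter
  nsamp <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(nsamp)) != 1)
    stop("signals with differing sampling rates are not supported")
  out <- matrix(0, nc, nsamp[1] * nrec)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", n = nsamp[ch], size = 2,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      out[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  rownames(out) <- labels
  list(data = out, fs = nsamp[1] / dur)
}
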