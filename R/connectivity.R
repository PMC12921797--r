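# FFT-based analytic signal: zero out negative frequencies, double the
# positive ones (DC and Nyquist untouched), inverse transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Analytic (complex) representation of band-limited epochs
#'
#' Computes, per channel and trial, the analytic signal `x + i * H(x)`
#' (Hilbert-transform quadrature via the FFT), whose argument is
#' the instantaneous phase. Because the Hilbert transform is circular, the
#' first and last `edge_frac` of the samples are flagged invalid and are
#' excluded from all downstream phase statistics.
#'
#' @param epochs a band-limited [epoch_set()].
#' @param edge_frac fraction of samples flagged at each edge (default 0.1).
#' @return An object of class `analytic_epochs`: list with the complex
#'   array `z` (`trials x channels x samples`), logical `valid` mask over
#'   samples, and the source metadata.
#' @export
analytic_signal <- function(epochs, edge_frac = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- n_trials(epochs); nc <- n_channels(epochs); ns <- n_samples(epochs)
  z <- array(complex(real = 0), c(nt, nc, ns))
  for (t in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      x <- epochs$data[t, ch, ]
      if (stats::sd(x) == 0)
        stop("channel ", epochs$channels[ch], " is constant in trial ", t,
             ": phase undefined")
      z[t, ch, ] <- hilbert_analytic(x)
    }
  }
  edge <- floor(edge_frac * ns)
  valid <- rep(TRUE, ns)
  if (edge > 0) valid[c(seq_len(edge), (ns - edge + 1):ns)] <- FALSE
  structure(list(z = z, valid = valid, fs = epochs$fs,
                 channels = epochs$channels, subject = epochs$subject,
                 group = epochs$group, condition = epochs$condition),
            class = "analytic_epochs")
}

#' Instantaneous phase of an analytic epoch set
#' @param analytic an `analytic_epochs` object.
#' @return numeric array of phases (radians), invalid edge samples NA.
#' @export
instantaneous_phase <- function(analytic) {
  ph <- Arg(analytic$z)
  ph[, , !analytic$valid] <- NA_real_
  ph
}

# wPLI core on one complex channels x samples matrix.
# wPLI(a,b) = |sum_k Im S_k| / sum_k |Im S_k|,  S_k = z_a,k * Conj(z_b,k);
# 0/0 (no imaginary cross-spectrum at all, e.g. identical signals) -> 0.
# The debiased variant removes the positive small-sample bias of the
# squared estimator (leave-one-out form) and returns its square root.
wpli_core <- function(Z, debias = FALSE) {
  C <- nrow(Z); S <- ncol(Z)
  X <- Re(Z); Y <- Im(Z)
  num <- Y %*% t(X) - X %*% t(Y)            # summed Im S, antisymmetric
  den <- matrix(0, C, C)
  sumsq <- if (debias) matrix(0, C, C)
  for (a in seq_len(C)) {
    ims <- X * matrix(Y[a, ], C, S, byrow = TRUE) -
           Y * matrix(X[a, ], C, S, byrow = TRUE)   # row b = Im S_{ab,k}... sign
    # note: rows are Im S_{a,b} with a fixed: Y_a X_b - X_a Y_b
    den[a, ] <- rowSums(abs(ims))
    if (debias) sumsq[a, ] <- rowSums(ims^2)
  }
  if (debias) {
    w2 <- (num^2 - sumsq) / (den^2 - sumsq)
    w2[!is.finite(w2)] <- 0
    w <- sqrt(pmax(w2, 0))
  } else {
    w <- abs(num) / den
    w[den == 0] <- 0
  }
  diag(w) <- 0
  w <- (w + t(w)) / 2       # symmetrize (exact up to fp noise)
  w
}

#' Weighted Phase Lag Index adjacency matrix
#'
#' Estimates the wPLI between every channel pair from the signed imaginary
#' part of the cross-spectrum, `|E[Im S]| / E[|Im S|]`. The estimate lies
#' in \[0, 1\], is exactly symmetric, has a zero diagonal, and is 0 by
#' convention when the denominator vanishes (no imaginary cross-spectrum,
#' e.g. identical or purely zero-lag signals) — the property that makes it
#' robust to volume conduction.
#'
#' By default the expectation runs over the valid within-trial time samples
#' of a single trial (single-trial matrices are the unit of the downstream
#' graph analysis). With `pool = TRUE` the valid samples of all trials are
#' pooled into one estimate, which is the appropriate mode when many short
#' trials are available and a single adjacency is wanted.
#'
#' @param analytic an `analytic_epochs` object.
#' @param trial trial index (default 1) when `pool = FALSE`.
#' @param pool pool valid samples across all trials.
#' @param debias use the debiased (bias-corrected squared) estimator;
#'   single-trial time-sample estimates are positively biased at small n.
#' @param min_samples minimum usable sample count (default 20).
#' @return Symmetric `channels x channels` matrix with dimnames.
#' @export
wpli_matrix <- function(analytic, trial = 1, pool = FALSE, debias = FALSE,
                        min_samples = 20) {
  stopifnot(inherits(analytic, "analytic_epochs"))
  v <- which(analytic$valid)
  if (pool) {
    nt <- dim(analytic$z)[1]
    Z <- do.call(cbind, lapply(seq_len(nt), function(t)
      matrix(analytic$z[t, , v], nrow = dim(analytic$z)[2])))
  } else {
    Z <- matrix(analytic$z[trial, , v], nrow = dim(analytic$z)[2])
  }
  if (ncol(Z) < min_samples)
    stop("fewer than ", min_samples, " usable samples")
  w <- wpli_core(Z, debias = debias)
  dimnames(w) <- list(analytic$channels, analytic$channels)
  w
}

#' All single-trial wPLI matrices of an epoch set
#'
#' @inheritParams wpli_matrix
#' @return `channels x channels x trials` array.
#' @export
wpli_matrices <- function(analytic, debias = FALSE, min_samples = 20) {
  nt <- dim(analytic$z)[1]
  out <- vapply(seq_len(nt), function(t)
    wpli_matrix(analytic, trial = t, debias = debias,
                min_samples = min_samples),
    matrix(0, length(analytic$channels), length(analytic$channels)))
  dimnames(out) <- list(analytic$channels, analytic$channels, NULL)
  out
}

#' Band-limited epochs to a subject-level connectivity representation
#'
#' Convenience wrapper: analytic signal, then wPLI. `mode = "trials"`
#' returns the stack of single-trial matrices (the default unit of
#' analysis), `"average"` their across-trial mean, `"pooled"` one estimate
#' over the pooled samples.
#'
#' @param band_epochs band-limited [epoch_set()].
#' @param mode see above. @param debias passed to the estimator.
#' @param subtract_evoked subtract the cross-trial mean (the phase-locked
#'   evoked response) from every trial before phase extraction, so the
#'   estimate reflects induced, ongoing coupling rather than
#'   stimulus-locked components shared by all channels. Requires >= 2
#'   trials.
#' @return array (`"trials"`) or matrix (otherwise).
#' @export
subject_connectivity <- function(band_epochs,
                                 mode = c("trials", "average", "pooled"),
                                 debias = FALSE, subtract_evoked = FALSE) {
  mode <- match.arg(mode)
  if (subtract_evoked) {
    if (n_trials(band_epochs) < 2)
      stop("evoked subtraction needs at least 2 trials")
    evoked <- apply(band_epochs$data, c(2, 3), mean)
    band_epochs$data <- band_epochs$data -
      aperm(array(evoked, c(dim(evoked), n_trials(band_epochs))), c(3, 1, 2))
  }
  an <- analytic_signal(band_epochs)
  switch(mode,
         trials  = wpli_matrices(an, debias = debias),
         average = {
           m <- wpli_matrices(an, debias = debias)
           apply(m, c(1, 2), mean)
         },
         pooled  = wpli_matrix(an, pool = TRUE, debias = debias))
}

#' Write a connectivity matrix as delimited text
#' @param w square matrix with channel dimnames. @param path output path.
#' @export
write_connectivity <- function(w, path) {
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
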