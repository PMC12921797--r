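#' Standard 40-sensor montage
#'
#' Returns the default sensor layout used throughout the package: a
#' 40-channel dry-electrode arrangement drawn from the international 10-10
#' and 10-20 systems, with 2-D head-plane positions (top view, nose up,
#' unit head radius) and a hemisphere label per sensor.
#'
#' @return A data.frame with columns `label`, `x`, `y` and `hemisphere`
#'   (`"L"`, `"R"` or `"M"` for midline).
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m)  # 40
standard_montage <- function() {
  tab <- c(
    "AF3", -0.30,  0.82, "AF4",  0.30,  0.82,
    "F7",  -0.81,  0.59, "F3",  -0.38,  0.55, "Fz",   0.00,  0.52,
    "F4",   0.38,  0.55, "F8",   0.81,  0.59,
    "FC5", -0.67,  0.30, "FC3", -0.45,  0.28, "FC1", -0.20,  0.27,
    "FC2",  0.20,  0.27, "FC4",  0.45,  0.28, "FC6",  0.67,  0.30,
    "FT9", -1.00,  0.38, "FT10", 1.00,  0.38,
    "T7",  -1.00,  0.00, "C5",  -0.75,  0.00, "C3",  -0.50,  0.00,
    "C1",  -0.25,  0.00, "Cz",   0.00,  0.00, "C2",   0.25,  0.00,
    "C4",   0.50,  0.00, "C6",   0.75,  0.00, "T8",   1.00,  0.00,
    "CP5", -0.67, -0.30, "CP3", -0.45, -0.28, "CP1", -0.20, -0.27,
    "CP2",  0.20, -0.27, "CP4",  0.45, -0.28, "CP6",  0.67, -0.30,
    "P7",  -0.81, -0.59, "P3",  -0.38, -0.55, "Pz",   0.00, -0.52,
    "P4",   0.38, -0.55, "P8",   0.81, -0.59,
    "PO3", -0.30, -0.82, "PO4",  0.30, -0.82,
    "O1",  -0.31, -0.95, "Oz",   0.00, -0.98, "O2",   0.31, -0.95
  )
  tab <- matrix(tab, ncol = 3, byrow = TRUE)
  m <- data.frame(
    label = tab[, 1],
    x = as.numeric(tab[, 2]),
    y = as.numeric(tab[, 3]),
    stringsAsFactors = FALSE
  )
  m$hemisphere <- montage_hemisphere(m$label)
  m
}

# Left/right/midline from the 10-10 naming convention: odd digit suffix =
# left, even = right, trailing 'z' = midline.
montage_hemisphere <- function(labels) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  hemi <- ifelse(grepl("z$", labels, ignore.case = TRUE), "M",
                 ifelse(num %% 2L == 1L, "L", "R"))
  if (anyNA(hemi)) stop("unparseable sensor label(s): ",
                        paste(labels[is.na(hemi)], collapse = ", "))
  hemi
}

#' Sensor neighborhood graph for cluster-based statistics
#'
#' Builds a spatial adjacency over the montage by Delaunay triangulation of
#' the 2-D sensor positions, then drops triangulation edges longer than
#' `prune` times the median Delaunay edge length. The pruning removes the
#' long sliver edges the triangulation creates along the convex hull, so
#' that "neighboring" retains its physical meaning on the cap.
#'
#' @param montage data.frame as returned by [standard_montage()].
#' @param prune edges longer than `prune` x median edge length are removed.
#' @return Symmetric logical matrix (sensors x sensors), dimnames = labels.
#' @export
montage_neighbors <- function(montage = standard_montage(), prune = 1.5) {
  stopifnot(is.data.frame(montage), nrow(montage) >= 3)
  dd <- deldir::deldir(montage$x, montage$y, suppressMsge = TRUE)
  seg <- dd$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  keep <- len <= prune * stats::median(len)
  n <- nrow(montage)
  adj <- matrix(FALSE, n, n, dimnames = list(montage$label, montage$label))
  for (i in which(keep)) {
    a <- seg$ind1[i]; b <- seg$ind2[i]
    adj[a, b] <- adj[b, a] <- TRUE
  }
  # pruning must not isolate a sensor: re-attach any isolate to its nearest
  # neighbour so the cluster search always covers the whole cap
  iso <- which(rowSums(adj) == 0)
  for (i in iso) {
    d <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
    d[i] <- Inf
    j <- which.min(d)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  adj
}

#' Canonical frequency band set
#'
#' The seven analysis bands: delta 1.5-4, theta 4-8, alpha 8-13, beta1
#' 13-20, beta2 20-30, gamma1 30-48 and gamma2 52-70 Hz. gamma1 stops at
#' 48 Hz and gamma2 starts at 52 Hz so that neither band straddles 50 Hz
#' line noise.
#'
#' @param names optional subset of band names to return.
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
default_bands <- function(names = NULL) {
  b <- data.frame(
    name    = c("delta", "theta", "alpha", "beta1", "beta2", "gamma1", "gamma2"),
    low_hz  = c(1.5, 4, 8, 13, 20, 30, 52),
    high_hz = c(4, 8, 13, 20, 30, 48, 70),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, b$name)
    if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "))
    b <- b[match(names, b$name), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

validate_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (nrow(bands) == 0) stop("empty band list")
  with(bands, {
    if (any(low_hz <= 0) || any(high_hz <= low_hz))
      stop("bands must satisfy 0 < low < high")
    if (any(high_hz >= fs / 2))
      stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  })
  invisible(bands)
}
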