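#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a BOLD series (steady-state
#' magnetization / T1 saturation period). The remaining data are unchanged.
#'
#' @param bold a [bold_series()].
#' @param n_discard number of leading volumes to drop (default 10).
#' @return the shortened [bold_series()].
#' @export
discard_initial <- function(bold, n_discard = 10L) {
  d <- dim(bold$data)
  if (n_discard >= d[4]) stop("cannot discard all volumes")
  if (n_discard > 0)
    bold$data <- bold$data[, , , -seq_len(n_discard), drop = FALSE]
  append_log(bold, sprintf("discard_initial(%d)", n_discard))
}

#' Friston 24-parameter motion regressor matrix
#'
#' Expands a 6-parameter rigid motion trace into the 24-column nuisance
#' design: the 6 parameters, the same 6 at the previous time point, and the
#' squares of both sets. The lagged block's first row is zero-filled.
#'
#' @param motion numeric matrix, t x 6 (3 translations mm, 3 rotations deg).
#' @return numeric matrix, t x 24, columns ordered
#'   `p1..p6, lag1..lag6, p1^2..p6^2, lag1^2..lag6^2`.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  if (!all(is.finite(motion))) stop("motion trace must be finite")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag, motion^2, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("lag", 1:6),
                     paste0("p", 1:6, "sq"), paste0("lag", 1:6, "sq"))
  out
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary least squares on an intercept plus the given regressors;
#' the residuals (orthogonal to every regressor column) replace the data.
#' Rank-deficient designs are reduced by dropping dependent columns with a
#' warning.
#'
#' @param bold a [bold_series()].
#' @param regressors numeric matrix with one row per remaining volume.
#' @return the residual [bold_series()].
#' @export
regress_nuisance <- function(bold, regressors) {
  Y <- series_matrix(bold)
  X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(X) != nrow(Y)) stop("regressor rows must match the number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("rank-deficient nuisance design: dropped %d dependent column(s)",
                    ncol(X) - qrX$rank))
    qrX <- qr(X[, sort(keep), drop = FALSE])
  }
  res <- qr.resid(qrX, Y)
  out <- matrix_to_bold(res, bold)
  append_log(out, sprintf("regress_nuisance(%d regressors)", ncol(regressors)))
}

#' Band-pass filter a BOLD series
#'
#' Linear detrend followed by rectangular frequency-domain masking: Fourier
#' bins with `low_hz <= f <= high_hz` are retained, all others (including DC)
#' are zeroed. This matches the hard-band convention of standard resting-state
#' toolboxes and makes the passband contract exact at bin frequencies.
#'
#' @param bold a [bold_series()].
#' @param low_hz,high_hz band edges in Hz (defaults 0.01 and 0.08).
#' @return the filtered [bold_series()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  TR <- bold$TR
  nyq <- 1 / (2 * TR)
  if (!(low_hz >= 0 && high_hz > low_hz && high_hz <= nyq))
    stop(sprintf("band must satisfy 0 <= low < high <= Nyquist (%.3f Hz)", nyq))
  Y <- series_matrix(bold)
  Y <- detrend_linear(Y)
  n <- nrow(Y)
  f <- fft_freqs(n, TR)
  keep <- abs(f) >= low_hz & abs(f) <= high_hz
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Yf <- Re(stats::mvfft(F, inverse = TRUE)) / n
  out <- matrix_to_bold(Yf, bold)
  append_log(out, sprintf("bandpass(%g-%g Hz)", low_hz, high_hz))
}

#' Signed FFT bin frequencies for n samples at sampling interval TR
#' @noRd
fft_freqs <- function(n, TR) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * TR)
}

#' Remove a per-column linear trend
#' @noRd
detrend_linear <- function(Y) {
  t <- seq_len(nrow(Y))
  X <- cbind(1, t - mean(t))
  qr.resid(qr(X), Y)
}

#' Framewise displacement from a motion trace
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' realignment parameters, with rotations converted from degrees to arc
#' length on a sphere of `head_radius` mm. The first frame's FD is 0.
#'
#' @param motion t x 6 matrix (translations mm, rotations degrees).
#' @param head_radius sphere radius for the rotation arc, mm (default 50).
#' @return list with `fd` (per-volume mm, first element 0) and `mean_fd`
#'   (mean over frames 2..t).
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  if (!all(is.finite(motion))) stop("motion trace must be finite")
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * pi / 180 * head_radius
  fd <- c(0, rowSums(abs(d)))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Head-motion exclusion check
#'
#' Fails a subject whose realignment parameters exceed the translation or
#' rotation limit on any axis at any time point (per-axis absolute maxima).
#'
#' @param motion t x 6 matrix (translations mm, rotations degrees).
#' @param max_trans translation limit, mm (default 2).
#' @param max_rot rotation limit, degrees (default 2).
#' @return list with `pass` (logical) and `reason` (character, "" on pass).
#' @export
exclusion_check <- function(motion, max_trans = 2.0, max_rot = 2.0) {
  motion <- as.matrix(motion)
  mt <- max(abs(motion[, 1:3]))
  mr <- max(abs(motion[, 4:6]))
  if (mt > max_trans)
    return(list(pass = FALSE,
                reason = sprintf("max |translation| %.2f mm > %.1f mm", mt, max_trans)))
  if (mr > max_rot)
    return(list(pass = FALSE,
                reason = sprintf("max |rotation| %.2f deg > %.1f deg", mr, max_rot)))
  list(pass = TRUE, reason = "")
}

#' Binarize a gray-matter probability map
#'
#' Threshold a probabilistic tissue map at a cutoff (strict `>`, matching the
#' `-thr`/`-bin` semantics of the usual command-line mask tool) to build the
#' analysis mask.
#'
#' @param prob 3-D array of probabilities in \[0, 1\].
#' @param cutoff probability cutoff (default 0.2).
#' @return list with `mask` (3-D 0/1 array) and `source_cutoff`.
#' @export
binarize_gm <- function(prob, cutoff = 0.2) {
  stopifnot(length(dim(prob)) == 3)
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  mask <- array(as.numeric(prob > cutoff), dim(prob))
  if (sum(mask) == 0) stop("empty gray-matter mask: nothing to analyze")
  list(mask = mask, source_cutoff = cutoff)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing of a 3-D map or every volume of a 4-D array,
#' with the kernel width given as full width at half maximum in mm
#' (sigma = fwhm / sqrt(8 ln 2) per axis, in voxel units through
#' `voxel_size`). Zero padding at the edges; an impulse supported in the
#' interior conserves its total sum.
#'
#' @param x 3-D or 4-D numeric array.
#' @param voxel_size length-3 voxel size in mm.
#' @param fwhm_mm kernel FWHM in mm (scalar; 0 is the identity).
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(x, voxel_size, fwhm_mm = 6) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(x)
  d <- dim(x)
  stopifnot(length(d) %in% c(3, 4))
  sigma <- fwhm_mm / (voxel_size * sqrt(8 * log(2)))
  for (ax in 1:3) x <- conv_axis(x, ax, gauss_kernel(sigma[ax]))
  x
}

#' @noRd
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(( -r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Convolve an array along one spatial axis (zero padded)
#' @noRd
conv_axis <- function(x, axis, kernel) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  # band (Toeplitz) matrix of the truncated kernel
  B <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  out <- B %*% m
  aperm(array(out, d[perm]), order(perm))
}

#' Run the standard preprocessing chain on one subject
#'
#' Applies, in the fixed published order: initial volume discard, nuisance
#' regression (Friston-24 motion expansion plus optional tissue signals), and
#' band-pass filtering. Returns both the nuisance-regressed series (full
#' spectrum, used for fALFF) and the band-passed series (used for the
#' correlation-based metrics), plus the framewise-displacement summary.
#'
#' @param bold a [bold_series()].
#' @param motion t x 6 motion trace matching the un-discarded series.
#' @param n_discard leading volumes to drop (default 10).
#' @param nuisance optional matrix of additional nuisance time courses
#'   (e.g. WM/CSF signals) matching the un-discarded series.
#' @param band band-pass edges in Hz.
#' @return list with elements `regressed` ([bold_series()]), `filtered`
#'   ([bold_series()]), `fd` (framewise displacement list) and `motion`
#'   (the trimmed trace).
#' @export
preprocess_subject <- function(bold, motion, n_discard = 10L,
                               nuisance = NULL, band = c(0.01, 0.08)) {
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == dim(bold$data)[4])
  b <- discard_initial(bold, n_discard)
  keep <- if (n_discard > 0) -seq_len(n_discard) else seq_len(nrow(motion))
  mt <- motion[keep, , drop = FALSE]
  X <- friston24(mt)
  if (!is.null(nuisance)) {
    X <- cbind(X, as.matrix(nuisance)[keep, , drop = FALSE])
  }
  reg <- regress_nuisance(b, X)
  filt <- bandpass(reg, band[1], band[2])
  list(regressed = reg, filtered = filt,
       fd = framewise_displacement(mt), motion = mt)
}
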