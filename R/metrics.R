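#' Fractional amplitude of low-frequency fluctuations
#'
#' For each mask voxel, the ratio of the summed square-root power spectrum in
#' the low-frequency band (0.01-0.08 Hz) to the summed square-root power over
#' the full positive-frequency range up to Nyquist (0.25 Hz at TR = 2 s). The
#' DC bin is excluded from both sums. Computed on the nuisance-regressed but
#' NOT band-passed series (the ratio needs the full spectrum).
#'
#' @param bold a [bold_series()] (nuisance-regressed; spatially smoothed first
#'   if the published smoothing order is wanted, see [compute_local_metrics()]).
#' @param mask 3-D analysis mask.
#' @param low_band low-frequency band in Hz.
#' @return a raw [metric_map()] with values in \[0, 1\].
#' @export
falff <- function(bold, mask, low_band = c(0.01, 0.08)) {
  Y <- series_matrix(bold, mask)
  n <- nrow(Y)
  if (n < 32) stop("series too short for a stable spectrum (need >= 32 points)")
  f <- fft_freqs(n, bold$TR)
  amp <- Mod(stats::mvfft(Y))
  pos <- f > 0
  lowb <- pos & f >= low_band[1] & f <= low_band[2]
  num <- colSums(amp[lowb, , drop = FALSE])
  den <- colSums(amp[pos, , drop = FALSE])
  zero <- den < .Machine$double.eps * n
  if (any(zero)) warning("all-zero series: fALFF set to 0")
  val <- ifelse(zero, 0, num / den)
  map_from_values(val, mask, "fALFF")
}

#' Kendall's coefficient of concordance of a set of time series
#'
#' The concordance of m rankings (one per series, ranks over time, average
#' ranks on ties): `w = (sum_i S_i^2 - n*mean(S)^2) / ((1/12) m^2 (n^3 - n))`
#' where `S_i` is the rank sum across the m series at time i. `w = 1` for
#' identical (or strictly monotone-equivalent) series. Series with zero
#' variance make the statistic degenerate; the result is 0 with a warning.
#'
#' @param series n x m matrix, one time series per column.
#' @return concordance in \[0, 1\].
#' @export
kcc <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series); m <- ncol(series)
  if (any(apply(series, 2, function(v) max(v) == min(v)))) {
    warning("constant series in KCC neighborhood: w set to 0")
    return(0)
  }
  R <- apply(series, 2, rank)
  S <- rowSums(R)
  num <- sum(S^2) - n * mean(S)^2
  num / ((1 / 12) * m^2 * (n^3 - n))
}

#' Regional homogeneity (voxelwise KCC over the 3x3x3 neighborhood)
#'
#' For each mask voxel, Kendall's coefficient of concordance between its time
#' series and those of its in-mask neighbors in the 27-voxel cube (the voxel
#' itself plus up to 26 neighbors); the normalization uses the actual number
#' of in-mask series, so boundary voxels keep a well-defined value in
#' \[0, 1\]. Computed on the band-passed, unsmoothed series.
#'
#' @param bold a band-passed [bold_series()].
#' @param mask 3-D analysis mask.
#' @return a raw [metric_map()] with values in \[0, 1\].
#' @export
reho <- function(bold, mask) {
  s <- dim(bold$data)[1:3]
  mask_l <- as.logical(mask)
  Y <- series_matrix(bold)[, mask_l, drop = FALSE]
  n <- nrow(Y)
  const <- apply(Y, 2, function(v) max(v) == min(v))
  if (any(const)) warning("constant series in mask: ReHo set to 0 there")
  R <- matrix(0, n, ncol(Y))
  R[, !const] <- apply(Y[, !const, drop = FALSE], 2, rank)

  # map full-grid flat index -> column in R (0 = off mask)
  col_of <- integer(prod(s))
  col_of[which(mask_l)] <- seq_len(sum(mask_l))
  idx <- arrayInd(which(mask_l), s)

  S <- matrix(0, n, ncol(Y))
  K <- integer(ncol(Y))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(idx, 2, offsets[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= s[1] & nb[, 2] >= 1 & nb[, 2] <= s[2] &
          nb[, 3] >= 1 & nb[, 3] <= s[3]
    cols <- integer(nrow(idx))
    cols[ok] <- col_of[flat_index(nb[ok, , drop = FALSE], s)]
    use <- cols > 0 & !const[pmax(cols, 1)]
    if (any(use)) {
      S[, use] <- S[, use] + R[, cols[use], drop = FALSE]
      K[use] <- K[use] + 1L
    }
  }
  num <- colSums(S^2) - n * colMeans(S)^2
  w <- ifelse(K >= 2 & !const, num / ((1 / 12) * K^2 * (n^3 - n)), 0)
  w[const] <- 0
  map_from_values(pmin(pmax(w, 0), 1), mask, "ReHo")
}

#' Weighted degree centrality
#'
#' For each mask voxel, the sum of its Pearson correlations with every other
#' mask voxel that exceed the threshold (`r > r_threshold`, positive tail
#' only); with `weighted = FALSE` the suprathreshold edge count instead.
#' Zero-variance voxels are excluded (their correlations count as 0).
#'
#' @param bold a band-passed, unsmoothed [bold_series()].
#' @param mask 3-D analysis mask (>= 2 voxels).
#' @param r_threshold correlation threshold (default 0.25).
#' @param weighted sum correlations (TRUE, default) or count edges.
#' @param block column-block size for the correlation sweep (memory control).
#' @return a raw [metric_map()], values >= 0.
#' @export
degree_centrality <- function(bold, mask, r_threshold = 0.25,
                              weighted = TRUE, block = 2000L) {
  pair_sweep(bold, mask, function(r, self) {
    r[self] <- 0
    keep <- r > r_threshold
    if (weighted) colSums(r * keep) else colSums(keep)
  }, metric = "DC", block = block)
}

#' Functional connectivity strength
#'
#' For each mask voxel i, `FC(i) = (1/(N-1)) * sum_{j != i, r_ij > r0}
#' atanh(r_ij)` where N is the total number of mask voxels; the denominator is
#' the full N - 1 regardless of how many pairs pass the threshold.
#'
#' @inheritParams degree_centrality
#' @param r0 correlation threshold (default 0.2).
#' @return a raw [metric_map()].
#' @export
fcs <- function(bold, mask, r0 = 0.2, block = 2000L) {
  N <- sum(as.logical(mask))
  pair_sweep(bold, mask, function(r, self) {
    r[self] <- 0
    keep <- r > r0
    colSums(fisher_z(r, warn = FALSE) * keep) / (N - 1)
  }, metric = "FCS", block = block)
}

#' Blockwise sweep over the voxel-voxel correlation matrix
#' @noRd
pair_sweep <- function(bold, mask, fun, metric, block = 2000L) {
  mask_l <- as.logical(mask)
  if (sum(mask_l) < 2) stop("need at least 2 mask voxels")
  Z <- scale_columns(series_matrix(bold)[, mask_l, drop = FALSE])
  V <- ncol(Z)
  out <- numeric(V)
  for (start in seq(1, V, by = block)) {
    cols <- start:min(start + block - 1, V)
    r <- crossprod(Z, Z[, cols, drop = FALSE])  # V x |cols|
    self <- cbind(cols, seq_along(cols))
    out[cols] <- fun(r, self)
  }
  map_from_values(out, mask, metric)
}

#' Voxel-mirrored homotopic connectivity
#'
#' Pearson correlation between each voxel's time series and that of its
#' mirror across the mid-sagittal plane. The mask is symmetrized first (a
#' voxel is kept iff its mirror is also in the mask), so the raw map is
#' mirror-symmetric by construction.
#'
#' @param bold a band-passed [bold_series()].
#' @param mask 3-D analysis mask.
#' @param grid the [grid_spec()] the data live on.
#' @return a raw correlation-valued [metric_map()] on the symmetrized mask.
#' @export
vmhc <- function(bold, mask, grid) {
  s <- grid$shape
  perm <- mirror_permutation(grid)
  mask_v <- as.logical(mask)
  sym <- mask_v & mask_v[perm]
  if (!any(sym)) stop("symmetrized mask is empty")
  Z <- scale_columns(series_matrix(bold))
  vox <- which(sym)
  r <- colSums(Z[, vox, drop = FALSE] * Z[, perm[vox], drop = FALSE])
  map_from_values(r, array(sym, s), "VMHC")
}

#' Standardize a metric map
#'
#' `fisher_z` applies atanh element-wise (only meaningful for
#' correlation-valued maps; inputs clipped to (-1, 1) with a warning);
#' `zscore` centers and scales by the within-mask mean and SD.
#'
#' @param map a [metric_map()].
#' @param method `"fisher_z"` or `"zscore"`.
#' @return the standardized [metric_map()].
#' @export
standardize_map <- function(map, method = c("zscore", "fisher_z")) {
  method <- match.arg(method)
  m <- map$mask
  v <- map$data[m]
  if (method == "fisher_z") {
    map$data[m] <- fisher_z(v)
  } else {
    sdv <- stats::sd(v)
    if (sdv < .Machine$double.eps) stop("zero within-mask SD: cannot z-score")
    map$data[m] <- (v - mean(v)) / sdv
  }
  map$standardized <- method
  map
}

#' @noRd
map_from_values <- function(values, mask, metric) {
  m <- as.logical(mask)
  arr <- array(0, dim(mask))
  arr[m] <- values
  metric_map(arr, metric, array(m, dim(mask)))
}

#' Smooth a metric map (marks the smoothing flag)
#'
#' @param map a [metric_map()].
#' @param voxel_size length-3 voxel size, mm.
#' @param fwhm_mm kernel FWHM, mm.
#' @return the smoothed [metric_map()].
#' @export
smooth_map <- function(map, voxel_size, fwhm_mm = 6) {
  map$data <- gaussian_smooth(map$data, voxel_size, fwhm_mm)
  map$smoothing_applied <- TRUE
  map
}

#' Compute the five local metrics with the published smoothing order
#'
#' fALFF is computed from the spatially smoothed, nuisance-regressed (full
#' spectrum) series and then z-scored; ReHo, DC, VMHC and FCS are computed
#' from the band-passed unsmoothed series, standardized (z-score for ReHo/DC/
#' FCS strength values, Fisher z for the correlation-valued VMHC followed by
#' z-scoring for comparability), and smoothed afterwards.
#'
#' @param pre result of [preprocess_subject()].
#' @param mask 3-D gray-matter mask.
#' @param grid the [grid_spec()].
#' @param which character vector of metrics to compute (subset of
#'   `c("falff", "reho", "dc", "vmhc", "fcs")`).
#' @param fwhm_mm smoothing kernel FWHM, mm (default 6).
#' @param r_dc DC correlation threshold; `r0` FCS threshold.
#' @param r0 FCS correlation threshold.
#' @return named list of standardized, smoothed [metric_map()]s, with a
#'   `smoothing_order` attribute recording per-metric step order.
#' @export
compute_local_metrics <- function(pre, mask, grid,
                                  which = c("falff", "reho", "dc", "vmhc", "fcs"),
                                  fwhm_mm = 6, r_dc = 0.25, r0 = 0.2) {
  out <- list()
  order_log <- list()
  if ("falff" %in% which) {
    sm <- pre$regressed
    sm$data <- gaussian_smooth(sm$data, grid$voxel_size, fwhm_mm)
    sm <- append_log(sm, sprintf("smooth(%gmm)", fwhm_mm))
    mp <- falff(sm, mask)
    mp$smoothing_applied <- TRUE  # input series smoothed before computation
    out$falff <- standardize_map(mp, "zscore")
    order_log$falff <- c("smooth", "compute", "standardize")
  }
  post_sm <- function(mp, std) {
    mp <- standardize_map(mp, std)
    smooth_map(mp, grid$voxel_size, fwhm_mm)
  }
  if ("reho" %in% which) {
    out$reho <- post_sm(reho(pre$filtered, mask), "zscore")
    order_log$reho <- c("compute", "standardize", "smooth")
  }
  if ("dc" %in% which) {
    out$dc <- post_sm(degree_centrality(pre$filtered, mask, r_dc), "zscore")
    order_log$dc <- c("compute", "standardize", "smooth")
  }
  if ("vmhc" %in% which) {
    mp <- standardize_map(vmhc(pre$filtered, mask, grid), "fisher_z")
    out$vmhc <- smooth_map(mp, grid$voxel_size, fwhm_mm)
    order_log$vmhc <- c("compute", "fisher_z", "smooth")
  }
  if ("fcs" %in% which) {
    out$fcs <- post_sm(fcs(pre$filtered, mask, r0), "zscore")
    order_log$fcs <- c("compute", "standardize", "smooth")
  }
  attr(out, "smoothing_order") <- order_log
  out
}
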