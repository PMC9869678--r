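#' Voxelwise covariate-adjusted two-sample t-test
#'
#' Per-voxel ordinary least squares of the metric value on
#' \[intercept, group indicator, covariates\]; the reported t-statistic is the
#' group coefficient over its standard error, with df = n - rank(design).
#' With no covariates this equals the pooled two-sample t exactly.
#'
#' @param stack numeric matrix, mask-voxels x subjects (one column per
#'   subject, values over the mask in column-major voxel order).
#' @param groups factor/character of "patient"/"control" per subject (the
#'   t-statistic is signed patient minus control).
#' @param covariates optional data.frame of numeric covariates (e.g. age,
#'   sex coded 0/1, mean FD); constant columns are rejected.
#' @param mask 3-D analysis mask matching the stack rows.
#' @param grid a [grid_spec()].
#' @return an object of class `stat_map`: list(t = 3-D array, df, design,
#'   residuals = voxels x subjects matrix, mask, grid).
#' @export
voxelwise_glm_ttest <- function(stack, groups, covariates = NULL, mask, grid) {
  g <- as.integer(factor(groups, levels = c("control", "patient"))) - 1L
  n <- length(g)
  stopifnot(ncol(stack) == n, sum(g) >= 3, sum(1 - g) >= 3)
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (!all(is.finite(cv))) stop("covariates must be finite")
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear design; offending columns among: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  df <- n - ncol(X)
  Yt <- t(stack)                      # subjects x voxels
  coef <- qr.coef(qrX, Yt)            # p x voxels
  res <- qr.resid(qrX, Yt)            # subjects x voxels
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- ifelse(se > 0, coef[2, ] / se, 0)
  tarr <- array(0, grid$shape)
  tarr[as.logical(mask)] <- tval
  structure(list(t = tarr, df = df, design = colnames(X),
                 residuals = t(res), mask = array(as.logical(mask), grid$shape),
                 grid = grid),
            class = "stat_map")
}

#' Estimate residual spatial smoothness (FWHM and RESELs)
#'
#' Per-axis smoothness of the model residuals from the lag-1 spatial
#' autocorrelation of standardized residuals: assuming a Gaussian spatial
#' autocorrelation, `FWHM_vox = sqrt(-2 ln 2 / ln rho1)`, floored at one
#' voxel (the lattice cannot express sub-voxel smoothness; for white noise
#' the estimate is the voxel size). The RESEL count is the mask volume in mm
#' divided by the product of the per-axis FWHMs in mm.
#'
#' @param residuals voxels-in-mask x images matrix of residuals (e.g. from
#'   [voxelwise_glm_ttest()]).
#' @param mask 3-D analysis mask.
#' @param grid a [grid_spec()].
#' @return list(fwhm = per-axis FWHM in mm, fwhm_vox, resels, n_mask).
#' @export
estimate_smoothness <- function(residuals, mask, grid) {
  s <- grid$shape
  mask_l <- array(as.logical(mask), s)
  if (ncol(residuals) < 2) stop("need at least 2 residual images")
  for (ax in 1:3) if (sum(apply(mask_l, ax, any)) < 2)
    stop("mask must span at least 2 voxels per axis")
  flat <- which(mask_l)
  idx <- arrayInd(flat, s)
  col_of <- integer(prod(s)); col_of[flat] <- seq_along(flat)
  # standardize each voxel's residual vector across images
  R <- residuals
  nrm <- sqrt(rowSums(R^2))
  ok_v <- nrm > 0
  R[ok_v, ] <- R[ok_v, ] / nrm[ok_v]
  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    nb <- idx; nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= s[ax]
    partner <- integer(nrow(idx)); partner[ok] <- col_of[flat_index(nb[ok, , drop = FALSE], s)]
    pair <- which(ok & partner > 0)
    a <- R[pair, , drop = FALSE]
    b <- R[partner[pair], , drop = FALSE]
    # rho1 over unit-norm voxel vectors: mean inner product
    rho1 <- sum(a * b) / length(pair)
    rho1 <- min(max(rho1, 0), 1 - 1e-12)
    fwhm_vox[ax] <- if (rho1 <= 0.25) 1 else sqrt(-2 * log(2) / log(rho1))
  }
  fwhm_mm <- fwhm_vox * grid$voxel_size
  n_mask <- length(flat)
  resels <- n_mask * prod(grid$voxel_size) / prod(fwhm_mm)
  list(fwhm = fwhm_mm, fwhm_vox = fwhm_vox, resels = resels, n_mask = n_mask)
}

#' Label connected components of a binary 3-D mask
#'
#' Breadth-first labelling under 6, 18 or 26-neighbor connectivity.
#'
#' @param bin 3-D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer 3-D array of component labels (0 = background).
#' @export
label_components <- function(bin, connectivity = 26) {
  s <- dim(bin)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  labels <- array(0L, s)
  todo <- which(bin)
  lab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      ci <- arrayInd(cur, s)
      for (o in seq_len(nrow(off))) {
        nb <- sweep(ci, 2, off[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= s[1] & nb[, 2] >= 1 & nb[, 2] <= s[2] &
              nb[, 3] >= 1 & nb[, 3] <= s[3]
        if (!any(ok)) next
        fi <- flat_index(nb[ok, , drop = FALSE], s)
        new <- fi[bin[fi] & labels[fi] == 0L]
        if (length(new)) {
          labels[new] <- lab
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' GRF cluster-level p-value for a cluster of k voxels
#'
#' Expected-Euler-characteristic approximation for a Gaussianized field:
#' the expected cluster count at threshold u is
#' `E[m] = R (4 ln 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2/2)` (R = RESELs),
#' the expected suprathreshold volume is `E[N] = S Phi(-u)` voxels, and the
#' cluster-size tail is `P(n >= k) = exp(-beta k^{2/3})` with
#' `beta = (Gamma(5/2) E[m] / E[N])^{2/3}`. The cluster p-value is
#' `1 - exp(-E[m] P(n >= k))`.
#' @noRd
grf_cluster_pvalue <- function(k, u, resels, n_mask) {
  Em <- resels * (4 * log(2))^1.5 * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(Em, 1e-12)
  EN <- n_mask * stats::pnorm(u, lower.tail = FALSE)
  En <- max(EN / Em, 1e-12)
  beta <- (gamma(2.5) / En)^(2 / 3)
  Pk <- exp(-beta * k^(2 / 3))
  1 - exp(-Em * Pk)
}

#' GRF cluster-extent thresholding of a t-map
#'
#' Voxels are thresholded two-sided at `voxel_p` (t-distribution with the
#' map's df), the t-field is Gaussianized, connected components are labelled
#' separately for positive and negative tails, and a cluster is kept iff its
#' GRF cluster-level probability is below `cluster_p`.
#'
#' @param stat a `stat_map` from [voxelwise_glm_ttest()].
#' @param smoothness result of [estimate_smoothness()] (estimated from the
#'   model residuals).
#' @param voxel_p two-sided voxel-forming p (default 0.001).
#' @param cluster_p cluster-level significance (default 0.01).
#' @param connectivity cluster connectivity rule (default 26).
#' @return list of clusters; each is a list(label, voxels = flat indices,
#'   size, peak_xyz = world mm, peak_t, direction, p_cluster).
#' @export
grf_cluster_threshold <- function(stat, smoothness, voxel_p = 0.001,
                                  cluster_p = 0.01, connectivity = 26) {
  tcrit <- stats::qt(1 - voxel_p / 2, stat$df)
  u <- stats::qnorm(1 - voxel_p / 2)
  out <- list()
  lab_total <- 0L
  for (sign_dir in c(1, -1)) {
    supra <- array(stat$mask & (sign_dir * stat$t > tcrit), dim(stat$t))
    if (!any(supra)) next
    labels <- label_components(supra, connectivity)
    for (l in seq_len(max(labels))) {
      vox <- which(labels == l)
      p_cl <- grf_cluster_pvalue(length(vox), u, smoothness$resels,
                                 smoothness$n_mask)
      if (p_cl >= cluster_p) next
      lab_total <- lab_total + 1L
      tv <- stat$t[vox]
      peak <- vox[which.max(abs(tv))]
      out[[lab_total]] <- list(
        label = lab_total, voxels = vox, size = length(vox),
        peak_xyz = as.numeric(voxel_to_world(arrayInd(peak, dim(stat$t)),
                                             stat$grid)),
        peak_t = tv[which.max(abs(tv))],
        direction = if (sign_dir > 0) "patient>control" else "patient<control",
        p_cluster = p_cl)
    }
  }
  out
}

#' Extract ROI-mean features from metric stacks
#'
#' For every metric and every one of its clusters, the mean of each subject's
#' standardized map over the cluster voxels; features are named
#' `<metric>@<label>`. Returns one row per subject with group labels and
#' covariates attached.
#'
#' @param stacks named list of voxels-in-mask x subjects matrices (one per
#'   metric; rows indexed by the mask's voxels in column-major order).
#' @param clusters named list (same names) of cluster lists from
#'   [grf_cluster_threshold()].
#' @param mask 3-D analysis mask the stacks are defined on.
#' @param meta data.frame with subject_id, group and covariate columns.
#' @return data.frame: subject_id, group, covariates, then one column per
#'   cluster feature.
#' @export
extract_features <- function(stacks, clusters, mask, meta) {
  flat <- which(as.logical(mask))
  row_of <- integer(length(as.logical(mask))); row_of[flat] <- seq_along(flat)
  feats <- list()
  for (mname in names(stacks)) {
    cl <- clusters[[mname]]
    if (is.null(cl) || !length(cl)) {
      message(sprintf("metric %s: no clusters, contributes no features", mname))
      next
    }
    for (c in cl) {
      rows <- row_of[c$voxels]
      if (any(rows == 0)) stop("cluster voxel outside the mask")
      vals <- colMeans(stacks[[mname]][rows, , drop = FALSE])
      feats[[sprintf("%s@%d", mname, c$label)]] <- vals
    }
  }
  if (!length(feats)) return(meta)
  out <- cbind(meta, as.data.frame(feats, optional = TRUE))
  names(out) <- c(names(meta), names(feats))
  out
}

#' Pooled two-sample t from summary statistics
#'
#' Textbook equal-variance two-sample t-test computed from per-group n, mean
#' and SD (as printed in a demographics table).
#'
#' @param n1,m1,s1 first group's size, mean, SD.
#' @param n2,m2,s2 second group's size, mean, SD.
#' @return list(t, df, p) with p two-sided.
#' @export
pooled_t_summary <- function(n1, m1, s1, n2, m2, s2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Chi-square goodness of fit against equal proportions
#'
#' For a within-group sex split k1:k2, the 1-df chi-square against a 50:50
#' expectation, without continuity correction.
#'
#' @param k1,k2 observed counts.
#' @return list(chisq, df, p).
#' @export
chisq_equal_props <- function(k1, k2) {
  e <- (k1 + k2) / 2
  x2 <- (k1 - e)^2 / e + (k2 - e)^2 / e
  list(chisq = x2, df = 1, p = stats::pchisq(x2, 1, lower.tail = FALSE))
}

#' Demographics comparison table
#'
#' Two-sample t-test on age between groups and, per group, a chi-square
#' goodness-of-fit of the sex split against equal proportions.
#'
#' @param meta data.frame with group ("patient"/"control"), age, sex ("M"/"F").
#' @return list(age = list(t, df, p), sex = named list per group of
#'   list(chisq, df, p, counts)).
#' @export
demographics_tests <- function(meta) {
  gr <- split(meta, meta$group)
  if (length(gr) != 2 || any(vapply(gr, nrow, 1L) < 2))
    stop("need two groups with at least 2 subjects each")
  a <- gr[[1]]$age; b <- gr[[2]]$age
  age <- pooled_t_summary(length(a), mean(a), stats::sd(a),
                          length(b), mean(b), stats::sd(b))
  sex <- lapply(gr, function(g) {
    k1 <- sum(g$sex == "M"); k2 <- sum(g$sex == "F")
    c(chisq_equal_props(k1, k2), list(counts = c(M = k1, F = k2)))
  })
  list(age = age, sex = sex, group_order = names(gr))
}
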