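#' Build metric stacks for a synthetic cohort (streaming, memory-bounded)
#'
#' Generates each subject in turn (deterministically from the master seed),
#' runs the preprocessing chain, computes the requested standardized metric
#' maps, and keeps only the per-subject mask values, so full 4-D volumes
#' never accumulate.
#'
#' @param n_patients,n_controls group sizes.
#' @param grid a [grid_spec()].
#' @param effects list of [effect_spec()].
#' @param noise a [noise_model()].
#' @param metrics subset of `c("falff", "reho", "dc", "vmhc", "fcs")` and/or
#'   `"seedfc"`.
#' @param seeds seed table for `"seedfc"` (defaults to [builtin_seeds()]
#'   remapped into the grid).
#' @param seed master seed.
#' @param n_discard leading volumes to drop.
#' @param fwhm_mm smoothing kernel, mm.
#' @return list(stacks = named list of mask-voxels x subjects matrices,
#'   meta = subject frame with age, sex (0/1), mean_fd, group,
#'   mask = 3-D mask, grid).
#' @export
cohort_metric_stacks <- function(n_patients, n_controls, grid = grid_spec(),
                                 effects = list(), noise = noise_model(),
                                 metrics = "falff", seeds = NULL, seed = 1L,
                                 n_discard = 10L, fwhm_mm = 6) {
  lapply(effects, effect_region, grid = grid)
  meta <- cohort_metadata(n_patients, n_controls, seed)
  gm <- gm_probability_map(grid)
  mask <- binarize_gm(gm)$mask
  local_metrics <- intersect(metrics, c("falff", "reho", "dc", "vmhc", "fcs"))
  want_seedfc <- "seedfc" %in% metrics
  if (want_seedfc && is.null(seeds)) seeds <- remap_seeds(builtin_seeds(), grid)
  stacks <- list()
  mean_fd <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    su <- generate_subject(meta[i, ], grid, effects, noise)
    pre <- preprocess_subject(su$bold, su$motion, n_discard = n_discard,
                              nuisance = su$nuisance)
    mean_fd[i] <- pre$fd$mean_fd
    maps <- compute_local_metrics(pre, mask, grid, which = local_metrics,
                                  fwhm_mm = fwhm_mm)
    if (want_seedfc) {
      sf <- seed_fc_all(pre$filtered, seeds, mask, grid)
      names(sf) <- paste0("seedfc_", names(sf))
      maps <- c(maps, lapply(sf, smooth_map,
                             voxel_size = grid$voxel_size, fwhm_mm = fwhm_mm))
    }
    for (mn in names(maps)) {
      if (is.null(stacks[[mn]]))
        stacks[[mn]] <- matrix(0, sum(mask), nrow(meta))
      stacks[[mn]][, i] <- maps[[mn]]$data[as.logical(mask)]
    }
  }
  meta$mean_fd <- mean_fd
  meta$sex01 <- as.integer(meta$sex == "M")
  list(stacks = stacks, meta = meta, mask = mask, grid = grid)
}

#' Run group statistics and feature extraction on metric stacks
#'
#' For each metric stack: covariate-adjusted voxelwise t-test, residual
#' smoothness estimation, GRF cluster-extent thresholding, then ROI-mean
#' feature extraction over the surviving clusters.
#'
#' When `split_aware` is a vector of training-row indices, the cluster-defining
#' statistics use only those subjects (avoiding the circularity of deriving
#' ROIs from all subjects before the train/test split); features are still
#' extracted for everyone.
#'
#' @param cm result of [cohort_metric_stacks()].
#' @param voxel_p,cluster_p GRF thresholds.
#' @param covariates character subset of c("age", "sex01", "mean_fd").
#' @param split_aware NULL (published behavior: ROIs from all subjects) or
#'   integer indices of the rows allowed to define clusters.
#' @return list(features = data.frame, clusters, stats) where `stats` holds
#'   each metric's `stat_map` and smoothness.
#' @export
group_analysis <- function(cm, voxel_p = 0.001, cluster_p = 0.01,
                           covariates = c("age", "sex01", "mean_fd"),
                           split_aware = NULL) {
  rows <- if (is.null(split_aware)) seq_len(nrow(cm$meta)) else split_aware
  covs <- cm$meta[rows, covariates, drop = FALSE]
  clusters <- list(); stats <- list()
  for (mn in names(cm$stacks)) {
    st <- voxelwise_glm_ttest(cm$stacks[[mn]][, rows, drop = FALSE],
                              cm$meta$group[rows], covs, cm$mask, cm$grid)
    sm <- estimate_smoothness(st$residuals, cm$mask, cm$grid)
    clusters[[mn]] <- grf_cluster_threshold(st, sm, voxel_p, cluster_p)
    stats[[mn]] <- list(stat = st, smoothness = sm)
  }
  feats <- extract_features(cm$stacks, clusters, cm$mask,
                            cm$meta[, c("subject_id", "group", "age", "sex01",
                                        "mean_fd")])
  list(features = feats, clusters = clusters, stats = stats)
}

#' Dice overlap between a cluster and a reference region
#'
#' @param cluster_voxels flat voxel indices of a cluster.
#' @param region 3-D logical reference mask.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(cluster_voxels, region) {
  ref <- which(as.logical(region))
  2 * length(intersect(cluster_voxels, ref)) /
    (length(cluster_voxels) + length(ref))
}

#' Simulate one null cohort of smooth maps and test for spurious clusters
#'
#' Generates per-subject 3-D Gaussian white-noise maps smoothed to a known
#' FWHM (no group effect), runs the covariate-free voxelwise t-test, residual
#' smoothness estimation and GRF cluster thresholding, and reports whether
#' any cluster survived -- one Monte-Carlo draw of the family-wise
#' false-positive indicator.
#'
#' @param n_patients,n_controls group sizes.
#' @param grid a [grid_spec()].
#' @param fwhm_mm applied smoothness, mm.
#' @param voxel_p,cluster_p GRF thresholds.
#' @param seed RNG seed.
#' @return list(any_cluster, n_clusters, smoothness).
#' @export
null_cluster_sim <- function(n_patients = 60, n_controls = 40,
                             grid = grid_spec(), fwhm_mm = 6,
                             voxel_p = 0.001, cluster_p = 0.01, seed = 1L) {
  n <- n_patients + n_controls
  mask <- array(TRUE, grid$shape)
  V <- prod(grid$shape)
  stack <- with_seed(seed, {
    arr <- array(stats::rnorm(V * n), c(grid$shape, n))
    arr <- gaussian_smooth(arr, grid$voxel_size, fwhm_mm)
    matrix(arr, V, n)
  })
  groups <- rep(c("patient", "control"), c(n_patients, n_controls))
  st <- voxelwise_glm_ttest(stack, groups, NULL, mask, grid)
  sm <- estimate_smoothness(st$residuals, mask, grid)
  cl <- grf_cluster_threshold(st, sm, voxel_p, cluster_p)
  list(any_cluster = length(cl) > 0, n_clusters = length(cl), smoothness = sm)
}
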