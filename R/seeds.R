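#' The 12 built-in network seeds
#'
#' The canonical seed set used for the 12 seed-based connectivity networks:
#' one 6 mm spherical seed per network at published MNI coordinates (default
#' mode, dorsal attention, left/right executive control, dorsal and ventral
#' motor, left/right salience, and primary/secondary visual networks).
#'
#' @return data.frame with columns network, region, x, y, z, radius.
#' @export
builtin_seeds <- function() {
  data.frame(
    network = c("DMN", "DAS", "ECN_L", "ECN_R",
                "Motor_dorsal_L", "Motor_dorsal_R",
                "Motor_ventral_L", "Motor_ventral_R",
                "Salience_L", "Salience_R",
                "Visual_primary", "Visual_secondary"),
    region = c("PCC", "IPS R", "Left DLPFC", "Right DLPFC",
               "Left precentral gyrus hand knob",
               "Right precentral gyrus hand knob",
               "Left precentral gyrus ventral",
               "Right precentral gyrus ventral",
               "Left anterior insula", "Right anterior insula",
               "BA17", "BA18"),
    x = c(2, 24, -42, 44, -28, 34, -56, 60, -32, 38, 8, -22),
    y = c(-54, -60, 34, 36, -26, -24, -6, -2, 26, 22, -78, -90),
    z = c(26, 50, 20, 20, 64, 60, 24, 24, -14, -10, 8, 2),
    radius = 6,
    stringsAsFactors = FALSE)
}

#' Read a seed table from CSV
#'
#' Expects columns network, region, x, y, z and optionally radius (default 6).
#' @param path CSV file path.
#' @return data.frame in [builtin_seeds()] layout.
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("network", "region", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("seed table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$radius)) df$radius <- 6
  df
}

#' Remap full-FOV seed coordinates into a reduced grid
#'
#' Linearly rescales standard-space coordinates (assumed to span about
#' +/-(90, 108, 72) mm) into the world bounding box of a desk-scale grid, so
#' the published seed layout can be exercised on small synthetic volumes. The
#' relative geometry (left/right, anterior/posterior ordering) is preserved;
#' absolute anatomy obviously is not.
#'
#' @param seeds a seed data.frame ([builtin_seeds()] layout).
#' @param grid a [grid_spec()].
#' @param margin fraction of the half-extent kept free at the edges.
#' @return the seed frame with rescaled x, y, z.
#' @export
remap_seeds <- function(seeds, grid, margin = 0.15) {
  full <- c(90, 108, 72)
  ctr <- voxel_centers(grid)
  half <- apply(abs(ctr), 2, max) * (1 - margin)
  for (i in 1:3) {
    seeds[[c("x", "y", "z")[i]]] <- seeds[[c("x", "y", "z")[i]]] / full[i] * half[i]
  }
  seeds
}

#' Voxel mask of a spherical seed
#'
#' Voxels whose world-coordinate centers lie within `radius` mm of the seed
#' center (coordinates interpreted through the grid affine).
#'
#' @param seed one row of a seed data.frame (needs x, y, z, radius, network).
#' @param grid a [grid_spec()].
#' @return 3-D 0/1 array; error if the sphere covers no voxel.
#' @export
seed_mask <- function(seed, grid) {
  m <- sphere_mask(grid, c(seed$x, seed$y, seed$z), seed$radius)
  if (!any(m))
    stop(sprintf("seed '%s' at (%g, %g, %g) lies outside the field of view",
                 seed$network, seed$x, seed$y, seed$z))
  array(as.numeric(m), grid$shape)
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation of the mean time series over the seed (restricted to
#' seed-and-gray-matter voxels) with every gray-matter voxel, Fisher
#' z-transformed.
#'
#' @param bold a preprocessed [bold_series()].
#' @param seed one row of a seed data.frame.
#' @param mask 3-D gray-matter mask.
#' @param grid a [grid_spec()].
#' @return a Fisher-z [metric_map()] named `seedFC:<network>`.
#' @export
seed_fc_map <- function(bold, seed, mask, grid) {
  sm <- seed_mask(seed, grid)
  joint <- as.logical(sm) & as.logical(mask)
  if (!any(joint)) stop(sprintf("seed '%s' does not overlap the mask", seed$network))
  Y <- series_matrix(bold)
  ref <- rowMeans(Y[, joint, drop = FALSE])
  if (stats::sd(ref) < .Machine$double.eps) stop("zero-variance seed mean series")
  refz <- (ref - mean(ref)) / sqrt(sum((ref - mean(ref))^2))
  Z <- scale_columns(Y[, as.logical(mask), drop = FALSE])
  r <- as.vector(crossprod(Z, refz))
  mp <- map_from_values(r, mask, paste0("seedFC:", seed$network))
  standardize_map(mp, "fisher_z")
}

#' All seed FC maps for one subject
#'
#' @param bold a preprocessed [bold_series()].
#' @param seeds seed data.frame (default [builtin_seeds()]).
#' @param mask 3-D gray-matter mask.
#' @param grid a [grid_spec()].
#' @return named list of [metric_map()]s, one per seed row.
#' @export
seed_fc_all <- function(bold, seeds = builtin_seeds(), mask, grid) {
  out <- lapply(seq_len(nrow(seeds)), function(i)
    seed_fc_map(bold, seeds[i, ], mask, grid))
  names(out) <- seeds$network
  out
}
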