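#' Define a 3-D acquisition grid
#'
#' A `grid_spec` describes the voxel lattice every volume in a study lives on:
#' its shape in voxels, the physical voxel size, the voxel-to-world affine, the
#' repetition time and the number of acquired volumes. The first (x) axis is
#' the left-right axis and must have even length so that every voxel has an
#' exact interhemispheric mirror.
#'
#' @param shape integer vector of length 3, voxels per axis (x, y, z).
#' @param voxel_size numeric vector of length 3, mm per voxel along each axis.
#' @param TR repetition time in seconds.
#' @param n_volumes number of time points acquired.
#' @param affine optional 4x4 voxel-to-world matrix (1-based voxel indices).
#'   Defaults to a diagonal affine that centers the grid on the world origin,
#'   so the mid-sagittal plane sits at world x = 0.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape = c(24L, 24L, 16L), voxel_size = c(3, 3, 3),
                      TR = 2, n_volumes = 180L, affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0),
            length(voxel_size) == 3, all(voxel_size > 0))
  if (shape[1] %% 2L != 0L)
    stop("left-right axis (shape[1]) must be even so every voxel has a mirror")
  if (!(TR > 0)) stop("TR must be positive")
  if (n_volumes < 20) stop("n_volumes must be at least 20")
  if (is.null(affine)) {
    # world(i) = voxel_size * i - voxel_size * (shape + 1) / 2  (1-based i),
    # which centers the grid at the origin and puts the mid-sagittal plane at x=0
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (shape + 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 affine = affine, TR = TR, n_volumes = as.integer(n_volumes)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels, %s mm, TR=%gs, %d volumes\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), x$TR, x$n_volumes))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Voxel index <-> world coordinate maps
#'
#' `voxel_to_world` maps 1-based voxel indices (rows of a matrix, or a single
#' length-3 vector) to world mm coordinates through the grid affine;
#' `world_to_voxel` is its inverse (continuous, not rounded).
#'
#' @param idx matrix (n x 3) or length-3 vector of 1-based voxel indices.
#' @param grid a [grid_spec()].
#' @return matrix (n x 3) of coordinates.
#' @export
voxel_to_world <- function(idx, grid) {
  idx <- rbind(idx)
  h <- cbind(idx, 1)
  w <- h %*% t(grid$affine)
  w[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz matrix (n x 3) or length-3 vector of world coordinates (mm).
#' @export
world_to_voxel <- function(xyz, grid) {
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1)
  v <- h %*% t(solve(grid$affine))
  v[, 1:3, drop = FALSE]
}

#' World coordinates of every voxel center
#' @param grid a [grid_spec()].
#' @return matrix (n_voxels x 3), rows in array (column-major) voxel order.
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  idx <- cbind(rep(seq_len(s[1]), times = s[2] * s[3]),
               rep(rep(seq_len(s[2]), each = s[1]), times = s[3]),
               rep(seq_len(s[3]), each = s[1] * s[2]))
  voxel_to_world(idx, grid)
}

#' Mirror a voxel across the mid-sagittal plane
#'
#' Reflects a 1-based voxel index across the grid's mid-sagittal (x) plane:
#' on an axis of even length n, index 1 maps to n, 2 to n-1, and so on. The
#' map is an involution and a bijection of the grid onto itself.
#'
#' @param index length-3 integer voxel index (1-based), or an n x 3 matrix.
#' @param grid a [grid_spec()].
#' @return mirrored index (same shape as input).
#' @export
mirror_voxel <- function(index, grid) {
  m <- rbind(index)
  if (any(m < 1) || any(m[, 1] > grid$shape[1]) ||
      any(m[, 2] > grid$shape[2]) || any(m[, 3] > grid$shape[3]))
    stop("voxel index out of grid")
  m[, 1] <- grid$shape[1] + 1L - m[, 1]
  if (is.null(dim(index))) m[1, ] else m
}

#' Linear (column-major) voxel ids for an n x 3 index matrix
#' @noRd
flat_index <- function(idx, shape) {
  idx <- rbind(idx)
  (idx[, 3] - 1L) * (shape[1] * shape[2]) + (idx[, 2] - 1L) * shape[1] + idx[, 1]
}

#' Mirror permutation of all voxels
#'
#' Returns the permutation p such that flat voxel v mirrors to p[v].
#' @noRd
mirror_permutation <- function(grid) {
  s <- grid$shape
  idx <- arrayInd(seq_len(prod(s)), s)
  flat_index(cbind(s[1] + 1L - idx[, 1], idx[, 2], idx[, 3]), s)
}
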