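# Small in-code fixtures shared across test files.

tiny_grid <- function(shape = c(6, 6, 4), n_volumes = 40, TR = 2)
  grid_spec(shape, c(3, 3, 3), TR = TR, n_volumes = n_volumes)

# a bold_series from a time-by-voxel matrix on a given grid
bold_from_matrix <- function(Y, grid) {
  stopifnot(ncol(Y) == prod(grid$shape))
  bold_series(aperm(array(Y, c(nrow(Y), grid$shape)), c(2, 3, 4, 1)),
              TR = grid$TR, affine = grid$affine)
}

# random bold series, seeded
random_bold <- function(grid, seed = 1, Tn = grid$n_volumes) {
  set.seed(seed)
  bold_from_matrix(matrix(rnorm(Tn * prod(grid$shape)), Tn), grid)
}

full_mask <- function(grid) array(TRUE, grid$shape)

# spherical region mask (world mm), duplicated here so acceptance tests do not
# rely on package internals
sphere_mask_for_test <- function(grid, center, radius) {
  ctr <- voxel_centers(grid)
  array(sqrt(rowSums(sweep(ctr, 2, center)^2)) <= radius, grid$shape)
}

with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small two-class feature set: one informative + noise features
toy_features <- function(n_per_class = 15, p_noise = 3, sep = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(1, 0), each = n_per_class)
  X <- cbind(sep * y + rnorm(n),
             matrix(rnorm(n * p_noise), n, p_noise))
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  list(X = X, y01 = y)
}
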