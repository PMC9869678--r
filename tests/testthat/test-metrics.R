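test_that("fALFF matches analytic limits and the DFT oracle", {
  g <- tiny_grid(c(4, 4, 2), n_volumes = 170)
  t <- (0:169) * 2
  V <- prod(g$shape)
  mask <- full_mask(g)
  # pure in-band sinusoid (0.05 Hz is an exact Fourier bin at T=170, TR=2)
  b_in <- bold_from_matrix(matrix(sin(2 * pi * 0.05 * t), 170, V), g)
  expect_gte(min(falff(b_in, mask)$data), 0.95)
  # pure out-of-band sinusoid
  b_out <- bold_from_matrix(matrix(sin(2 * pi * 0.15 * t), 170, V), g)
  expect_lte(max(falff(b_out, mask)$data), 0.05)
  # random series agree with the O(n^2) DFT oracle
  set.seed(4)
  Y <- matrix(rnorm(170 * V), 170, V)
  got <- falff(bold_from_matrix(Y, g), mask)$data
  for (v in c(1, 9, V)) {
    expect_equal(as.vector(got)[v], oracle_falff(Y[, v], TR = 2),
                 tolerance = 1e-10)
  }
  # white noise: expected ratio ~ (# low bins)/(# positive bins)
  nlow <- sum(seq(1, 85) / 340 >= 0.01 & seq(1, 85) / 340 <= 0.08)
  expect_equal(mean(got), nlow / 85, tolerance = 0.02)
  # all-zero series -> 0 with warning
  expect_warning(z <- falff(bold_from_matrix(matrix(0, 170, V), g), mask),
                 "all-zero")
  expect_equal(max(abs(z$data)), 0)
})

test_that("KCC reaches 1 for concordant series and matches the Spearman oracle", {
  set.seed(5)
  base <- rnorm(20)
  ident <- matrix(base, 20, 27)
  expect_equal(kcc(ident), 1)
  # strictly monotone transforms preserve ranks -> still 1
  mono <- sapply(1:27, function(k) exp(k * 0.1 * base) + k)
  expect_equal(kcc(mono), 1)
  # random case vs independent pairwise-Spearman identity
  Y <- matrix(rnorm(20 * 27), 20, 27)
  expect_equal(kcc(Y), oracle_kcc_spearman(Y), tolerance = 1e-12)
  expect_true(kcc(Y) >= 0 && kcc(Y) <= 1)
  expect_warning(w0 <- kcc(cbind(rep(1, 20), Y[, 1:3])), "constant")
  expect_equal(w0, 0)
})

test_that("reho equals per-voxel KCC of the in-mask 27-neighborhood", {
  g <- tiny_grid(c(6, 4, 3), n_volumes = 25)
  set.seed(6)
  Y <- matrix(rnorm(25 * prod(g$shape)), 25)
  mask <- array(TRUE, g$shape)
  mask[1, 1, ] <- FALSE                      # irregular mask edge
  got <- reho(bold_from_matrix(Y, g), mask)
  expect_true(all(got$data[mask] >= 0 & got$data[mask] <= 1))
  s <- g$shape
  for (v in sample(which(mask), 12)) {
    ci <- arrayInd(v, s)
    nb <- as.matrix(expand.grid(ci[1] + (-1:1), ci[2] + (-1:1), ci[3] + (-1:1)))
    ok <- nb[, 1] >= 1 & nb[, 1] <= s[1] & nb[, 2] >= 1 & nb[, 2] <= s[2] &
          nb[, 3] >= 1 & nb[, 3] <= s[3]
    nb <- nb[ok, , drop = FALSE]
    flat <- nb[, 1] + (nb[, 2] - 1) * s[1] + (nb[, 3] - 1) * s[1] * s[2]
    flat <- flat[mask[flat]]
    expect_equal(got$data[v], oracle_kcc_spearman(Y[, flat]),
                 tolerance = 1e-10, info = paste("voxel", v))
  }
})

test_that("degree centrality matches the hand toy and the O(V^2) oracle", {
  # 3-voxel toy with controlled correlations via explicit construction
  g3 <- grid_spec(c(2, 2, 1), n_volumes = 200)
  set.seed(8)
  n <- 200
  e <- matrix(rnorm(n * 4), n, 4)
  base <- scale(e[, 1])
  mix <- function(r, noise) r * base + sqrt(1 - r^2) * scale(noise)
  Y <- cbind(base, mix(0.9, e[, 2]), mix(0.3, e[, 3]), 0)
  # oracle on the realized correlations
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), g3$shape)
  got <- degree_centrality(bold_from_matrix(Y, g3), mask, 0.25)
  expect_equal(got$data[mask], oracle_dc(Y[, 1:3], 0.25), tolerance = 1e-10)
  # larger random case
  g <- tiny_grid(c(6, 5, 4), n_volumes = 30)
  set.seed(9)
  Y <- matrix(rnorm(30 * prod(g$shape)), 30)
  mask <- array(runif(prod(g$shape)) < 0.6, g$shape)
  mask[1, 1, 1] <- TRUE; mask[2, 1, 1] <- TRUE
  got <- degree_centrality(bold_from_matrix(Y, g), mask, 0.25, block = 37)
  expect_equal(got$data[mask], oracle_dc(Y[, mask], 0.25), tolerance = 1e-10)
  expect_true(all(got$data[mask] >= 0))
  # binary variant counts edges
  gotb <- degree_centrality(bold_from_matrix(Y, g), mask, 0.25, weighted = FALSE)
  expect_true(all(gotb$data[mask] == floor(gotb$data[mask])))
})

test_that("FCS matches Eq-style hand computation and the brute-force oracle", {
  g <- tiny_grid(c(6, 5, 4), n_volumes = 30)
  set.seed(10)
  Y <- matrix(rnorm(30 * prod(g$shape)), 30)
  mask <- array(runif(prod(g$shape)) < 0.5, g$shape)
  mask[1:2, 1, 1] <- TRUE
  got <- fcs(bold_from_matrix(Y, g), mask, 0.2, block = 23)
  expect_equal(got$data[mask], oracle_fcs(Y[, mask], 0.2), tolerance = 1e-10)
  # no suprathreshold pair -> all zeros (orthogonal sinusoid phases)
  t <- 1:64
  Yo <- sapply(1:8, function(k) sin(2 * pi * k * t / 64))
  g8 <- grid_spec(c(2, 2, 2), n_volumes = 64)
  z <- fcs(bold_from_matrix(Yo, g8), full_mask(g8), 0.2)
  expect_equal(max(abs(z$data)), 0)
})

test_that("VMHC is mirror-symmetric, near zero for independent hemispheres", {
  g <- tiny_grid(c(6, 4, 3), n_volumes = 120)
  set.seed(11)
  V <- prod(g$shape)
  # duplicated hemispheres plus independent noise -> exact symmetry
  Y <- matrix(rnorm(120 * V), 120, V)
  perm <- vapply(seq_len(V), function(v) {
    ci <- arrayInd(v, g$shape)
    mirrored <- mirror_voxel(ci[1, ], g)
    mirrored[1] + (mirrored[2] - 1) * 6 + (mirrored[3] - 1) * 24
  }, numeric(1))
  Ysym <- Y + Y[, perm]
  mask <- full_mask(g)
  got <- vmhc(bold_from_matrix(Ysym, g), mask, g)
  expect_equal(max(abs(got$data - got$data[6:1, , , drop = FALSE])), 0)
  # oracle agreement, voxel loop
  for (v in c(1, 10, 40)) {
    expect_equal(got$data[v], cor(Ysym[, v], Ysym[, perm[v]]),
                 tolerance = 1e-10)
  }
  # independent hemispheres: mean VMHC within 3 SE of 0
  goti <- vmhc(bold_from_matrix(Y, g), mask, g)
  se <- 1 / sqrt(120 - 3)
  expect_lt(abs(mean(goti$data)), 3 * se)
  # identical mirrored series: Fisher z clipped, finite (no overflow)
  Yd <- Y[, pmin(seq_len(V), perm)]   # each voxel equals its mirror exactly
  zm <- suppressWarnings(
    standardize_map(vmhc(bold_from_matrix(Yd, g), mask, g), "fisher_z"))
  expect_true(all(is.finite(zm$data)))
  expect_gt(min(zm$data), 5)          # near the clip bound atanh(1 - 1e-7)
})

test_that("standardize_map implements both conventions", {
  g <- tiny_grid(c(4, 4, 2))
  mask <- full_mask(g)
  set.seed(12)
  r <- array(runif(prod(g$shape), -0.9, 0.9), g$shape)
  mp <- metric_map(r, "VMHC", mask)
  fz <- standardize_map(mp, "fisher_z")
  expect_equal(fz$data[1], atanh(r[1]))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0), 0)
  zs <- standardize_map(mp, "zscore")
  expect_equal(mean(zs$data[mask]), 0, tolerance = 1e-10)
  expect_equal(sd(zs$data[mask]), 1, tolerance = 1e-10)
  expect_error(standardize_map(metric_map(array(1, dim(mask)), "x", mask),
                               "zscore"), "zero within-mask SD")
})

test_that("compute_local_metrics records the published smoothing order", {
  g <- tiny_grid(c(6, 6, 4), n_volumes = 60)
  co <- generate_cohort(2, 2, g, seed = 13)
  su <- co$subjects[[1]]
  pre <- preprocess_subject(su$bold, su$motion, n_discard = 5,
                            nuisance = su$nuisance)
  maps <- compute_local_metrics(pre, full_mask(g), g,
                                which = c("falff", "reho"))
  ord <- attr(maps, "smoothing_order")
  expect_equal(ord$falff, c("smooth", "compute", "standardize"))
  expect_equal(ord$reho, c("compute", "standardize", "smooth"))
  expect_true(maps$falff$smoothing_applied)
  expect_true(maps$reho$smoothing_applied)
})
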