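test_that("covariate-free GLM t equals the closed-form pooled t", {
  g <- tiny_grid(c(4, 4, 2))
  mask <- full_mask(g)
  set.seed(16)
  n1 <- 7; n2 <- 9
  stack <- matrix(rnorm(prod(g$shape) * (n1 + n2)), prod(g$shape))
  groups <- rep(c("patient", "control"), c(n1, n2))
  st <- voxelwise_glm_ttest(stack, groups, NULL, mask, g)
  expect_equal(st$df, n1 + n2 - 2)
  for (v in c(1, 8, 32)) {
    expect_equal(st$t[v],
                 oracle_pooled_t(stack[v, groups == "patient"],
                                 stack[v, groups == "control"]),
                 tolerance = 1e-10)
  }
  # with covariates the df drops by the added columns
  cov <- data.frame(age = rnorm(n1 + n2), sex01 = rbinom(n1 + n2, 1, 0.5),
                    mean_fd = runif(n1 + n2))
  st2 <- voxelwise_glm_ttest(stack, groups, cov, mask, g)
  expect_equal(st2$df, n1 + n2 - 5)
  expect_error(voxelwise_glm_ttest(stack, groups,
                                   data.frame(a = cov$age, b = 2 * cov$age),
                                   mask, g), "collinear")
})

test_that("permuted null labels give ~5% voxelwise false positives", {
  g <- tiny_grid(c(8, 8, 6))
  mask <- full_mask(g)
  set.seed(17)
  stack <- matrix(rnorm(prod(g$shape) * 30), prod(g$shape))
  fracs <- sapply(1:5, function(i) {
    groups <- sample(rep(c("patient", "control"), c(15, 15)))
    st <- voxelwise_glm_ttest(stack, groups, NULL, mask, g)
    mean(2 * pt(-abs(st$t[mask]), st$df) < 0.05)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("smoothness estimation recovers applied and absent smoothing", {
  g <- grid_spec(c(40, 40, 24), c(3, 3, 3), n_volumes = 20)
  mask <- full_mask(g)
  set.seed(18)
  n_img <- 8
  V <- prod(g$shape)
  smooth_stack <- sapply(seq_len(n_img), function(i)
    as.vector(gaussian_smooth(array(rnorm(V), g$shape), g$voxel_size, 6)))
  est <- estimate_smoothness(smooth_stack, mask, g)
  expect_true(all(abs(est$fwhm - 6) / 6 < 0.15))
  white_stack <- matrix(rnorm(V * n_img), V)
  est_w <- estimate_smoothness(white_stack, mask, g)
  expect_true(all(abs(est_w$fwhm - 3) / 3 < 0.15))
  # doubling voxel size doubles FWHM in mm exactly
  g2 <- grid_spec(g$shape, c(6, 6, 6), n_volumes = 20)
  est2 <- estimate_smoothness(smooth_stack, mask, g2)
  expect_equal(est2$fwhm, 2 * est$fwhm, tolerance = 1e-12)
  expect_equal(est$resels, V * 27 / prod(est$fwhm))
})

test_that("component labelling matches the flood-fill oracle", {
  set.seed(19)
  for (conn in c(6, 18, 26)) {
    bin <- array(runif(8 * 7 * 6) < 0.25, c(8, 7, 6))
    got <- label_components(bin, conn)
    want <- oracle_label(bin, conn)
    expect_true(same_partition(got, want), info = paste("connectivity", conn))
    expect_equal(got > 0, bin, ignore_attr = TRUE)
  }
})

test_that("GRF thresholding keeps an injected blob and rejects null data", {
  g <- grid_spec(c(16, 16, 12), c(3, 3, 3), n_volumes = 20)
  mask <- full_mask(g)
  V <- prod(g$shape)
  set.seed(20)
  n1 <- 15; n2 <- 15
  blob <- as.logical(seed_mask(
    data.frame(network = "b", x = 0, y = 0, z = 0, radius = 8), g))
  stack <- sapply(seq_len(n1 + n2), function(i)
    as.vector(gaussian_smooth(array(rnorm(V), g$shape), g$voxel_size, 5)))
  stack[blob, seq_len(n1)] <- stack[blob, seq_len(n1)] + 1.2
  groups <- rep(c("patient", "control"), c(n1, n2))
  st <- voxelwise_glm_ttest(stack, groups, NULL, mask, g)
  sm <- estimate_smoothness(st$residuals, mask, g)
  cl <- grf_cluster_threshold(st, sm)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$direction, "patient>control")
  expect_gt(dice_overlap(cl[[1]]$voxels, blob), 0.5)
  expect_gt(cl[[1]]$peak_t, 0)
  expect_lt(cl[[1]]$p_cluster, 0.01)
  # absurdly strict voxel threshold on NULL data -> empty list, not an error
  null_stack <- stack
  null_stack[blob, seq_len(n1)] <- null_stack[blob, seq_len(n1)] - 1.2
  st0 <- voxelwise_glm_ttest(null_stack, groups, NULL, mask, g)
  sm0 <- estimate_smoothness(st0$residuals, mask, g)
  expect_equal(length(grf_cluster_threshold(st0, sm0, voxel_p = 1e-12)), 0)
})

test_that("extract_features averages standardized maps over cluster voxels", {
  g <- tiny_grid(c(4, 4, 2))
  mask <- array(FALSE, g$shape); mask[1:3, 1:3, 1] <- TRUE
  set.seed(21)
  n <- 6
  stack <- matrix(rnorm(sum(mask) * n), sum(mask), n)
  flat <- which(mask)
  clusters <- list(m1 = list(
    list(label = 1, voxels = flat[c(1, 3, 5)], size = 3),
    list(label = 2, voxels = flat[2], size = 1)))
  meta <- data.frame(subject_id = paste0("s", 1:n),
                     group = rep(c("patient", "control"), 3))
  ft <- extract_features(list(m1 = stack), clusters, mask, meta)
  expect_equal(ft[["m1@1"]], colMeans(stack[c(1, 3, 5), ]))
  expect_equal(ft[["m1@2"]], stack[2, ])          # single voxel
  # constant map -> feature equals the constant
  cstack <- matrix(7, sum(mask), n)
  ftc <- extract_features(list(m1 = cstack), clusters, mask, meta)
  expect_true(all(ftc[["m1@1"]] == 7))
  # metric with no clusters contributes no columns
  expect_message(ft2 <- extract_features(list(m1 = stack, m2 = stack),
                                         list(m1 = clusters$m1, m2 = list()),
                                         mask, meta), "no clusters")
  expect_false(any(grepl("^m2@", names(ft2))))
})

test_that("demographics tests reproduce the published summary statistics", {
  # printed cohort summaries: n=40 (40.3 +/- 9.9) vs n=60 (46.0 +/- 14.8)
  r <- pooled_t_summary(40, 40.3, 9.9, 60, 46.0, 14.8)
  expect_equal(round(r$t, 1), -2.1)
  expect_lt(r$p, 0.05)
  # control-group sex split 21:19 vs equal proportions
  x <- chisq_equal_props(21, 19)
  expect_equal(round(x$chisq, 1), 0.1)
  expect_equal(round(x$p, 2), 0.75)
  # equal means and SDs -> t = 0
  expect_equal(pooled_t_summary(10, 5, 2, 12, 5, 2)$t, 0)
  # wrapper on a metadata frame
  meta <- data.frame(group = rep(c("patient", "control"), c(6, 5)),
                     age = c(rnorm(6, 46, 10), rnorm(5, 40, 10)),
                     sex = sample(c("M", "F"), 11, replace = TRUE))
  d <- demographics_tests(meta)
  a <- meta$age[meta$group == "control"]; b <- meta$age[meta$group == "patient"]
  expect_equal(d$age$t, oracle_pooled_t(a, b), tolerance = 1e-10)
  expect_error(demographics_tests(meta[1:6, ]), "two groups")
})
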