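test_that("generate_cohort is bit-identical under a fixed seed", {
  g <- tiny_grid(n_volumes = 24)
  eff <- effect_spec("local_synchrony", c(0, 0, 0), 5, 1)
  c1 <- generate_cohort(2, 2, g, list(eff), seed = 11)
  c2 <- generate_cohort(2, 2, g, list(eff), seed = 11)
  expect_identical(c1$meta, c2$meta)
  for (i in seq_along(c1$subjects)) {
    expect_identical(c1$subjects[[i]]$bold$data, c2$subjects[[i]]$bold$data)
    expect_identical(c1$subjects[[i]]$motion, c2$subjects[[i]]$motion)
  }
  c3 <- generate_cohort(2, 2, g, list(eff), seed = 12)
  expect_false(identical(c1$subjects[[1]]$bold$data, c3$subjects[[1]]$bold$data))
})

test_that("effect regions outside the grid are rejected", {
  g <- tiny_grid()
  bad <- effect_spec("falff_amplitude", c(500, 0, 0), 3, 1)
  expect_error(generate_cohort(2, 2, g, list(bad)), "outside the grid")
  expect_error(effect_spec("seed_coupling", c(0, 0, 0), 5, 1), "partner")
  expect_error(effect_spec("falff_amplitude", c(0, 0, 0), 5, -1))
})

test_that("subject structure is well-formed", {
  g <- tiny_grid(n_volumes = 24)
  co <- generate_cohort(2, 3, g, seed = 5)
  expect_equal(nrow(co$meta), 5)
  expect_equal(sum(co$meta$group == "patient"), 2)
  su <- co$subjects[[1]]
  expect_s3_class(su$bold, "bold_series")
  expect_equal(dim(su$bold$data), c(g$shape, 24))
  expect_equal(dim(su$motion), c(24, 6))
  expect_true(all(su$gm_prob >= 0 & su$gm_prob <= 1))
  expect_true(all(co$meta$age >= 18 & co$meta$age <= 80))
})

test_that("gm blob covers the requested fraction above the cutoff", {
  g <- grid_spec(c(20, 20, 12))
  gm <- gm_probability_map(g, coverage = 0.6)
  expect_equal(mean(gm > 0.2), 0.6, tolerance = 0.01)
  expect_error(binarize_gm(array(0, c(4, 4, 4))), "empty")
})

test_that("motion stays under exclusion limits by default; violator flag works", {
  g <- tiny_grid(n_volumes = 40)
  co <- generate_cohort(2, 2, g, seed = 2)
  for (su in co$subjects) expect_true(exclusion_check(su$motion)$pass)
  cv <- generate_cohort(2, 2, g, seed = 2,
                        noise = noise_model(force_motion_violator = TRUE))
  fails <- vapply(cv$subjects, function(s) !exclusion_check(s$motion)$pass,
                  logical(1))
  expect_true(any(fails))
})

test_that("injected fALFF effect raises patient in-region fALFF in every cohort", {
  g <- tiny_grid(c(8, 8, 6), n_volumes = 60)
  eff <- effect_spec("falff_amplitude", c(-4, 0, 0), 6, magnitude = 2)
  for (seed in 1:3) {
    co <- generate_cohort(10, 10, g, list(eff), seed = seed)
    region <- as.logical(seed_mask(
      data.frame(network = "e", x = -4, y = 0, z = 0, radius = 6), g))
    vals <- vapply(co$subjects, function(su) {
      pre <- preprocess_subject(su$bold, su$motion, n_discard = 4,
                                nuisance = su$nuisance)
      mp <- falff(pre$regressed, full_mask(g))
      mean(mp$data[region])
    }, numeric(1))
    pat <- co$meta$group == "patient"
    expect_gt(mean(vals[pat]), mean(vals[!pat]))
  }
})

test_that("in-region metric group difference is monotone in effect magnitude", {
  # one seeded cohort per magnitude x target, small grid; averaged over seeds
  g <- tiny_grid(c(8, 8, 6), n_volumes = 60)
  region_df <- data.frame(network = "e", x = -4, y = 0, z = 0, radius = 6)
  region <- as.logical(seed_mask(region_df, g))
  mags <- c(0, 1, 3)
  gap <- function(target, mag, seed) {
    eff <- if (target == "seed_coupling")
      effect_spec(target, c(-4, 0, 0), 6, mag, partner_center = c(4, 6, 0))
    else effect_spec(target, c(-4, 0, 0), 6, mag)
    co <- generate_cohort(6, 6, g, list(eff), seed = seed)
    vals <- vapply(co$subjects, function(su) {
      pre <- preprocess_subject(su$bold, su$motion, n_discard = 4,
                                nuisance = su$nuisance)
      mp <- switch(target,
        falff_amplitude = falff(pre$regressed, full_mask(g)),
        local_synchrony = reho(pre$filtered, full_mask(g)),
        homotopic_coupling = vmhc(pre$filtered, full_mask(g), g),
        hub_degree = degree_centrality(pre$filtered, full_mask(g)))
      mean(mp$data[region])
    }, numeric(1))
    pat <- co$meta$group == "patient"
    mean(vals[pat]) - mean(vals[!pat])
  }
  for (target in c("falff_amplitude", "local_synchrony", "homotopic_coupling",
                   "hub_degree")) {
    gaps <- vapply(mags, function(m)
      mean(vapply(1:3, function(s) gap(target, m, s), numeric(1))), numeric(1))
    expect_true(all(diff(gaps) > 0),
                info = sprintf("%s gaps: %s", target,
                               paste(round(gaps, 3), collapse = ", ")))
  }
})

test_that("seed_coupling effect raises seed-FC in the coupled region", {
  g <- tiny_grid(c(8, 8, 6), n_volumes = 60)
  seed_df <- data.frame(network = "src", x = 4, y = 6, z = 0, radius = 6)
  region_df <- data.frame(network = "tgt", x = -4, y = 0, z = 0, radius = 6)
  region <- as.logical(seed_mask(region_df, g))
  gapmag <- function(mag) {
    eff <- effect_spec("seed_coupling", c(-4, 0, 0), 6, mag,
                       partner_center = c(4, 6, 0))
    co <- generate_cohort(6, 6, g, list(eff), seed = 9)
    vals <- vapply(co$subjects, function(su) {
      pre <- preprocess_subject(su$bold, su$motion, n_discard = 4,
                                nuisance = su$nuisance)
      fcm <- seed_fc_map(pre$filtered, seed_df, full_mask(g), g)
      mean(fcm$data[region])
    }, numeric(1))
    pat <- co$meta$group == "patient"
    mean(vals[pat]) - mean(vals[!pat])
  }
  gaps <- vapply(c(0, 1, 3), gapmag, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("null cohort voxelwise t-tests have nominal size", {
  g <- tiny_grid(c(8, 8, 6), n_volumes = 40)
  co <- generate_cohort(10, 10, g, seed = 21)
  mask <- full_mask(g)
  stack <- sapply(co$subjects, function(su) {
    pre <- preprocess_subject(su$bold, su$motion, n_discard = 4,
                              nuisance = su$nuisance)
    as.vector(falff(pre$regressed, mask)$data)
  })
  st <- voxelwise_glm_ttest(stack, co$meta$group, NULL, mask, g)
  p <- 2 * pt(-abs(st$t[mask]), st$df)
  frac <- mean(p < 0.05)
  # binomial tolerance on 384 (correlated) voxels; generous band
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("write_cohort emits a readable text manifest", {
  g <- tiny_grid(n_volumes = 24)
  co <- generate_cohort(2, 2, g, seed = 4)
  dir <- file.path(tempdir(), "cohort_out")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 4)
  Y <- as.matrix(read.table(man$bold_path[1]))
  expect_equal(unname(Y), unname(series_matrix(co$subjects[[1]]$bold)),
               tolerance = 1e-12)
})
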