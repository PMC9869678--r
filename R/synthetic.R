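#' Specify an injectable group effect
#'
#' An effect modifies the generative parameters of the patient group inside a
#' spherical region (world mm coordinates), giving downstream analyses a known
#' ground truth. Targets map onto the metric families:
#' `falff_amplitude` (extra low-frequency power), `local_synchrony` (a shared
#' low-frequency source across the region's voxels), `hub_degree` (the region's
#' source is also coupled weakly to all gray matter), `homotopic_coupling`
#' (the source is shared with the region's mirror), and `seed_coupling` (the
#' source is shared with a partner region).
#'
#' @param target one of `"falff_amplitude"`, `"local_synchrony"`,
#'   `"hub_degree"`, `"homotopic_coupling"`, `"seed_coupling"`.
#' @param center world-mm center of the spherical region.
#' @param radius sphere radius, mm.
#' @param magnitude non-negative dimensionless effect scale (signal SD added,
#'   in units of the white-noise SD).
#' @param direction `"patient_up"` (patients receive the effect) or
#'   `"patient_down"` (controls receive it, so patients are relatively lower).
#' @param partner_center,partner_radius partner sphere for
#'   `seed_coupling` (required for that target).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(target, center, radius, magnitude,
                        direction = c("patient_up", "patient_down"),
                        partner_center = NULL, partner_radius = NULL) {
  target <- match.arg(target, c("falff_amplitude", "local_synchrony",
                                "hub_degree", "homotopic_coupling",
                                "seed_coupling"))
  direction <- match.arg(direction)
  stopifnot(length(center) == 3, radius > 0, magnitude >= 0)
  if (target == "seed_coupling" && is.null(partner_center))
    stop("seed_coupling requires a partner_center")
  structure(list(target = target, center = as.numeric(center),
                 radius = radius, magnitude = magnitude,
                 direction = direction,
                 partner_center = partner_center,
                 partner_radius = if (is.null(partner_radius)) radius
                                  else partner_radius),
            class = "effect_spec")
}

#' Noise-model parameters for the synthetic generator
#'
#' @param sigma_white white-noise SD (the unit of all other amplitudes).
#' @param background_amp SD of the per-voxel independent band-limited
#'   (0.01-0.08 Hz) background oscillation present everywhere.
#' @param nuisance_amp SD of the two global WM/CSF-like nuisance components.
#' @param motion_step_trans,motion_step_rot random-walk step SDs for the
#'   motion trace (mm, degrees).
#' @param drift_coupling amplitude of the motion-derived drift component.
#' @param force_motion_violator if TRUE, motion steps are inflated so subjects
#'   exceed the 2 mm / 2 deg exclusion limits (for testing the exclusion path).
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(sigma_white = 1, background_amp = 0.6,
                        nuisance_amp = 0.5, motion_step_trans = 0.02,
                        motion_step_rot = 0.02, drift_coupling = 0.4,
                        force_motion_violator = FALSE) {
  structure(list(sigma_white = sigma_white, background_amp = background_amp,
                 nuisance_amp = nuisance_amp,
                 motion_step_trans = motion_step_trans,
                 motion_step_rot = motion_step_rot,
                 drift_coupling = drift_coupling,
                 force_motion_violator = force_motion_violator),
            class = "noise_model")
}

#' Band-limited Gaussian noise columns
#'
#' White Gaussian noise hard-band-limited to `band` in the frequency domain,
#' then rescaled to unit SD per column (zero columns if the band holds no
#' bins).
#'
#' @param n time points.
#' @param TR sampling interval, s.
#' @param band frequency band, Hz.
#' @param ncol number of independent columns.
#' @return n x ncol matrix.
#' @export
bandlimited_noise <- function(n, TR, band = c(0.01, 0.08), ncol = 1) {
  W <- matrix(stats::rnorm(n * ncol), n, ncol)
  f <- fft_freqs(n, TR)
  keep <- abs(f) >= band[1] & abs(f) <= band[2]
  if (!any(keep)) return(matrix(0, n, ncol))
  F <- stats::mvfft(W)
  F[!keep, ] <- 0
  X <- Re(stats::mvfft(F, inverse = TRUE)) / n
  sd <- sqrt(colSums(sweep(X, 2, colMeans(X))^2) / (n - 1))
  sd[sd == 0] <- 1
  sweep(X, 2, sd, "/")
}

#' Smooth gray-matter probability blob
#'
#' A deterministic ellipsoidal probability blob calibrated so that exactly
#' `coverage` of the grid exceeds probability 0.2 (exercising the binarization
#' cutoff).
#'
#' @param grid a [grid_spec()].
#' @param coverage fraction of voxels with probability > 0.2 (default 0.6).
#' @return 3-D array of probabilities in \[0, 1\].
#' @export
gm_probability_map <- function(grid, coverage = 0.6) {
  s <- grid$shape
  idx <- arrayInd(seq_len(prod(s)), s)
  rho2 <- rowSums(sweep(sweep(idx, 2, (s + 1) / 2), 2, s / 2, "/")^2)
  thr <- stats::quantile(rho2, coverage, names = FALSE)
  k <- -log(0.2) / thr
  array(exp(-k * rho2), s)
}

#' Spherical voxel mask around a world-coordinate center
#' @noRd
sphere_mask <- function(grid, center, radius) {
  ctr <- voxel_centers(grid)
  d2 <- rowSums(sweep(ctr, 2, center)^2)
  inside <- d2 <= radius^2
  array(inside, grid$shape)
}

effect_region <- function(eff, grid) {
  m <- sphere_mask(grid, eff$center, eff$radius)
  if (!any(m))
    stop(sprintf("effect region (center %s, radius %g) lies outside the grid",
                 paste(eff$center, collapse = ","), eff$radius))
  m
}

#' Cohort metadata (demographics and per-subject seeds)
#'
#' Draws ages from Normal(43, 12) truncated to \[18, 80\] and sex as a fair
#' Bernoulli, and assigns each subject a seed derived from the master seed, so
#' that a subject's data can be regenerated independently of the others.
#'
#' @param n_patients,n_controls group sizes (>= 2 each).
#' @param seed master seed.
#' @return data.frame with subject_id, group, age, sex, subject_seed.
#' @export
cohort_metadata <- function(n_patients, n_controls, seed = 1L) {
  stopifnot(n_patients >= 2, n_controls >= 2)
  n <- n_patients + n_controls
  with_seed(derive_seed(seed, "metadata"), {
    age <- stats::rnorm(n, 43, 12)
    while (any(bad <- age < 18 | age > 80))
      age[bad] <- stats::rnorm(sum(bad), 43, 12)
    sex <- stats::rbinom(n, 1, 0.5)
    data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = rep(c("patient", "control"), c(n_patients, n_controls)),
      age = round(age, 1),
      sex = ifelse(sex == 1, "M", "F"),
      subject_seed = vapply(seq_len(n),
                            function(i) derive_seed(seed, paste0("subject", i)),
                            integer(1)),
      stringsAsFactors = FALSE)
  })
}

#' Generate one synthetic subject
#'
#' The BOLD signal is the sum of (a) independent per-voxel band-limited
#' (0.01-0.08 Hz) oscillations, (b) two global WM/CSF-like nuisance time
#' courses with smooth spatial weights, (c) a motion-derived drift, (d) white
#' Gaussian noise, and (e) the injected effect components for the subject's
#' group. Deterministic given `meta_row$subject_seed`.
#'
#' @param meta_row one row of [cohort_metadata()].
#' @param grid a [grid_spec()].
#' @param effects list of [effect_spec()].
#' @param noise a [noise_model()].
#' @return list: subject_id, group, age, sex, bold ([bold_series()]),
#'   motion (t x 6), nuisance (t x 2 known confound courses),
#'   gm_prob (3-D array).
#' @export
generate_subject <- function(meta_row, grid, effects = list(),
                             noise = noise_model()) {
  s <- grid$shape; V <- prod(s); Tn <- grid$n_volumes; TR <- grid$TR
  regions <- lapply(effects, effect_region, grid = grid)
  with_seed(meta_row$subject_seed, {
    step_t <- noise$motion_step_trans
    step_r <- noise$motion_step_rot
    if (noise$force_motion_violator) { step_t <- step_t * 30; step_r <- step_r * 30 }
    motion <- apply(matrix(stats::rnorm(Tn * 6), Tn, 6) *
                      rep(c(step_t, step_r), each = Tn * 3)[seq_len(Tn * 6)],
                    2, cumsum)
    motion <- matrix(motion, Tn, 6)

    Y <- matrix(stats::rnorm(Tn * V, sd = noise$sigma_white), Tn, V)
    Y <- Y + bandlimited_noise(Tn, TR, c(0.01, 0.08), V) * noise$background_amp

    # WM/CSF-like global components: low-frequency courses, smooth weights
    nuis <- bandlimited_noise(Tn, TR, c(0.005, 0.1), 2)
    for (k in 1:2) {
      w <- gaussian_smooth(array(stats::rnorm(V), s), grid$voxel_size, 9)
      w <- as.vector(w) / max(stats::sd(w), 1e-12)
      Y <- Y + noise$nuisance_amp * (nuis[, k, drop = FALSE] %*% t(w))
    }

    # motion-derived drift
    mstd <- scale(motion)
    mstd[is.nan(mstd)] <- 0
    drift <- rowSums(mstd) / sqrt(6)
    wd <- gaussian_smooth(array(stats::rnorm(V), s), grid$voxel_size, 9)
    wd <- abs(as.vector(wd)) / max(stats::sd(wd), 1e-12)
    Y <- Y + noise$drift_coupling * (cbind(drift) %*% t(wd))

    gm <- gm_probability_map(grid)
    gm_vox <- as.vector(gm) > 0.2

    affected <- (meta_row$group == "patient")
    for (ei in seq_along(effects)) {
      eff <- effects[[ei]]
      gets_effect <- if (eff$direction == "patient_up") affected else !affected
      if (!gets_effect || eff$magnitude == 0) next
      rg <- which(as.vector(regions[[ei]]))
      if (eff$target == "falff_amplitude") {
        Y[, rg] <- Y[, rg] +
          eff$magnitude * bandlimited_noise(Tn, TR, c(0.01, 0.08), length(rg))
      } else {
        src <- bandlimited_noise(Tn, TR, c(0.01, 0.08), 1)
        Y[, rg] <- Y[, rg] + eff$magnitude * src[, rep(1, length(rg))]
        if (eff$target == "hub_degree") {
          remote <- setdiff(which(gm_vox), rg)
          Y[, remote] <- Y[, remote] +
            0.3 * eff$magnitude * src[, rep(1, length(remote))]
        } else if (eff$target == "homotopic_coupling") {
          mir <- mirror_permutation(grid)[rg]
          add <- setdiff(mir, rg)
          Y[, add] <- Y[, add] + eff$magnitude * src[, rep(1, length(add))]
        } else if (eff$target == "seed_coupling") {
          pm <- sphere_mask(grid, eff$partner_center, eff$partner_radius)
          if (!any(pm)) stop("seed_coupling partner region outside the grid")
          add <- setdiff(which(as.vector(pm)), rg)
          Y[, add] <- Y[, add] + eff$magnitude * src[, rep(1, length(add))]
        }
      }
    }

    bold <- bold_series(aperm(array(Y, c(Tn, s)), c(2, 3, 4, 1)),
                        TR = TR, affine = grid$affine, log = "simulated")
    list(subject_id = meta_row$subject_id, group = meta_row$group,
         age = meta_row$age, sex = meta_row$sex, bold = bold,
         motion = motion, nuisance = nuis, gm_prob = gm)
  })
}

#' Generate a reproducible two-group synthetic BOLD cohort
#'
#' @inheritParams cohort_metadata
#' @inheritParams generate_subject
#' @param seed master seed; identical seeds give bit-identical cohorts.
#' @return list with `subjects` (list of subject records), `meta`
#'   (the [cohort_metadata()] frame), `grid`, `effects`.
#' @export
generate_cohort <- function(n_patients, n_controls, grid = grid_spec(),
                            effects = list(), noise = noise_model(),
                            seed = 1L) {
  lapply(effects, effect_region, grid = grid)  # validate early
  meta <- cohort_metadata(n_patients, n_controls, seed)
  subjects <- lapply(seq_len(nrow(meta)), function(i)
    generate_subject(meta[i, ], grid, effects, noise))
  list(subjects = subjects, meta = meta, grid = grid, effects = effects)
}

#' Write a cohort to plain-text files
#'
#' Writes, per subject, the BOLD series as a whitespace-delimited matrix
#' (volumes in rows, voxels in columns, column-major voxel order), the motion
#' trace (6 columns), the shared gray-matter probability map, and a manifest
#' CSV (subject_id, group, age, sex, paths).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm_path <- file.path(dir, "gm_prob.tsv")
  utils::write.table(matrix(as.vector(cohort$subjects[[1]]$gm_prob), nrow = 1),
                     gm_path, row.names = FALSE, col.names = FALSE)
  rows <- lapply(cohort$subjects, function(su) {
    bp <- file.path(dir, paste0(su$subject_id, "_bold.tsv"))
    mp <- file.path(dir, paste0(su$subject_id, "_motion.tsv"))
    utils::write.table(series_matrix(su$bold), bp,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(su$motion, mp, row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = su$subject_id, group = su$group, age = su$age,
               sex = su$sex, bold_path = bp, motion_path = mp,
               gm_path = gm_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
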