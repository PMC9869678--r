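#' Derive a stage-specific RNG seed from a master seed
#'
#' Every stochastic stage in the package draws its seed from one master seed
#' plus a stage tag, so a single `--seed` reproduces a whole run while stages
#' remain decoupled (adding a stage does not shift another stage's stream).
#'
#' @param seed master integer seed.
#' @param tag character stage name.
#' @return an integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, tag) {
  u <- utf8ToInt(as.character(tag))
  h <- sum(u * seq_along(u) * 97)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded package internals do not perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fisher z-transform with clipping
#'
#' atanh of a correlation, with |r| clipped to 1 - 1e-7 (warning) so perfect
#' correlations map to a large finite z instead of Inf.
#'
#' @param r numeric vector of correlations.
#' @param clip clipping bound on |r|.
#' @param warn warn when clipping occurs.
#' @return atanh of the clipped values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7, warn = TRUE) {
  out_of_range <- abs(r) >= 1 - 1e-12
  if (any(out_of_range, na.rm = TRUE) && warn)
    warning("correlations at +/-1 clipped before Fisher z-transform")
  atanh(pmin(pmax(r, -clip), clip))
}

#' Columnwise standardization to zero mean, unit norm
#'
#' Scales each column of a time-by-voxel matrix so that crossprod gives
#' Pearson correlations; all-constant columns are set to zero (their
#' correlations are treated as 0).
#' @noRd
scale_columns <- function(Y) {
  Y <- sweep(Y, 2, colMeans(Y), "-")
  nrm <- sqrt(colSums(Y^2))
  bad <- nrm < .Machine$double.eps * nrow(Y)
  nrm[bad] <- 1
  Y <- sweep(Y, 2, nrm, "/")
  Y[, bad] <- 0
  attr(Y, "zero_variance") <- bad
  Y
}
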