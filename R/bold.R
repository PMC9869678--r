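#' A subject's 4-D BOLD series
#'
#' Container for one subject's BOLD data on a [grid_spec()] lattice, with the
#' repetition time, affine and an append-only log of processing steps.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param TR repetition time, seconds.
#' @param affine 4x4 voxel-to-world matrix.
#' @param log character vector of steps already applied.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, TR, affine, log = character()) {
  stopifnot(length(dim(data)) == 4, TR > 0)
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, TR = TR, affine = as.matrix(affine), log = log),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_series: %dx%dx%d voxels, %d volumes, TR=%gs\n",
              d[1], d[2], d[3], d[4], x$TR))
  if (length(x$log)) cat("  steps:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

append_log <- function(bold, step) {
  bold$log <- c(bold$log, step)
  bold
}

#' Extract the time-by-voxel matrix of a BOLD series
#'
#' @param bold a [bold_series()].
#' @param mask optional 3-D logical/0-1 array; columns are restricted to mask
#'   voxels (in column-major order).
#' @return numeric matrix, time points in rows.
#' @export
series_matrix <- function(bold, mask = NULL) {
  d <- dim(bold$data)
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = d[4])
  if (!is.null(mask)) Y <- Y[, as.logical(mask), drop = FALSE]
  Y
}

#' Rebuild a bold_series from a time-by-voxel matrix
#' @noRd
matrix_to_bold <- function(Y, template) {
  d <- dim(template$data)
  d[4] <- nrow(Y)
  template$data <- aperm(array(Y, dim = c(nrow(Y), d[1], d[2], d[3])),
                         c(2, 3, 4, 1))
  template
}

#' A voxelwise scalar metric map
#'
#' @param data 3-D numeric array (zero off-mask).
#' @param metric metric name, e.g. "fALFF", "ReHo", "DC", "VMHC", "FCS" or
#'   "seedFC:<network>".
#' @param mask 3-D logical/0-1 array of defined voxels.
#' @param standardized one of "raw", "fisher_z", "zscore".
#' @param smoothing_applied has spatial smoothing been applied to this map?
#' @return an object of class `metric_map`.
#' @export
metric_map <- function(data, metric, mask,
                       standardized = "raw", smoothing_applied = FALSE) {
  stopifnot(length(dim(data)) == 3)
  standardized <- match.arg(standardized, c("raw", "fisher_z", "zscore"))
  m <- as.logical(mask)
  if (!all(is.finite(data[m]))) stop("metric map must be finite on the mask")
  structure(list(data = data, metric = metric, mask = array(m, dim(data)),
                 standardized = standardized,
                 smoothing_applied = isTRUE(smoothing_applied)),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map %s [%s%s]: %d mask voxels\n", x$metric,
              x$standardized, if (x$smoothing_applied) ", smoothed" else "",
              sum(x$mask)))
  invisible(x)
}
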