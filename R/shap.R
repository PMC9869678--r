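#' Shapley-value feature contributions of a model
#'
#' Shapley values of a prediction function over feature coalitions, with the
#' conditional value of a coalition S approximated by replacing the features
#' outside S with background rows and averaging the predictions (the usual
#' interventional Kernel-SHAP value function). With `p <= exact_limit`
#' features all `2^p` coalitions are enumerated and the Shapley formula is
#' evaluated exactly, so the local-accuracy (efficiency) identity
#' `base + sum(phi) = f(x)` holds to machine precision; with more features a
#' seeded kernel-weighted regression over sampled coalitions is used, with
#' the efficiency constraint enforced exactly in the solver.
#'
#' @param f prediction function taking a feature matrix, returning a numeric
#'   score per row (e.g. `function(X) svm_decision(model, X)`).
#' @param background feature matrix of background rows (the reference
#'   distribution; typically the training rows).
#' @param explain feature matrix of rows to explain.
#' @param seed RNG seed (sampled-coalition path).
#' @param exact_limit maximum p for exact enumeration (default 12).
#' @param nsamples coalition samples when p > exact_limit (default 2048).
#' @return an object of class `shap_summary`: list(values = n x p matrix of
#'   signed contributions, base_value, mean_abs, order, feature_names,
#'   fx = model outputs on `explain`).
#' @export
shap_contributions <- function(f, background, explain, seed = 1L,
                               exact_limit = 12L, nsamples = 2048L) {
  background <- as.matrix(background)
  explain <- as.matrix(explain)
  if (ncol(background) != ncol(explain))
    stop("feature mismatch: background has ", ncol(background),
         " columns, explain has ", ncol(explain))
  p <- ncol(explain)
  nm <- colnames(explain)
  if (is.null(nm)) nm <- paste0("f", seq_len(p))
  fx <- as.numeric(f(explain))
  base <- mean(as.numeric(f(background)))
  vals <- if (p <= exact_limit)
    shap_exact(f, background, explain, p)
  else
    shap_sampled(f, background, explain, p, fx, base, nsamples, seed)
  colnames(vals) <- nm
  mean_abs <- colMeans(abs(vals))
  ord <- order(-mean_abs, nm)
  structure(list(values = vals, base_value = base, mean_abs = mean_abs,
                 order = ord, feature_names = nm, fx = fx),
            class = "shap_summary")
}

#' @noRd
shap_exact <- function(f, background, explain, p) {
  nb <- nrow(background)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  sizes <- rowSums(masks)
  # Shapley weight for adding feature i to a coalition of size s (of the
  # remaining p-1): s! (p-s-1)! / p!
  wgt <- exp(lgamma(0:p + 1) + lgamma(p - (0:p)) - lgamma(p + 1))
  vals <- matrix(0, nrow(explain), p)
  for (e in seq_len(nrow(explain))) {
    x <- explain[e, ]
    v <- numeric(nrow(masks))
    for (s in seq_len(nrow(masks))) {
      Z <- background
      on <- masks[s, ]
      if (any(on)) Z[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
      v[s] <- mean(f(Z))
    }
    # subset id arithmetic: mask row s corresponds to bits (s-1)
    bit <- 2^(seq_len(p) - 1)
    id <- as.integer(masks %*% bit)
    v_of <- numeric(2^p); v_of[id + 1] <- v
    for (i in seq_len(p)) {
      without <- which(!masks[, i])
      sid <- id[without]
      vals[e, i] <- sum(wgt[sizes[without] + 1] *
                          (v_of[sid + bit[i] + 1] - v_of[sid + 1]))
    }
  }
  vals
}

#' @noRd
shap_sampled <- function(f, background, explain, p, fx, base, nsamples, seed) {
  nb <- nrow(background)
  sizes <- 1:(p - 1)
  kw <- (p - 1) / (choose(p, sizes) * sizes * (p - sizes))
  size_prob <- kw * choose(p, sizes)
  size_prob <- size_prob / sum(size_prob)
  vals <- matrix(0, nrow(explain), p)
  with_seed(seed, {
    Zmask <- matrix(FALSE, nsamples, p)
    ssz <- sample(sizes, nsamples, replace = TRUE, prob = size_prob)
    for (k in seq_len(nsamples)) Zmask[k, sample.int(p, ssz[k])] <- TRUE
  })
  w <- 1 / (ssz * (p - ssz))   # kernel weight given the size was sampled
  for (e in seq_len(nrow(explain))) {
    x <- explain[e, ]
    v <- vapply(seq_len(nsamples), function(k) {
      Z <- background
      on <- Zmask[k, ]
      Z[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
      mean(f(Z))
    }, numeric(1))
    # weighted regression of v - base on the masks, with the efficiency
    # constraint sum(phi) = fx - base eliminated into the design
    tot <- fx[e] - base
    A <- Zmask[, -p, drop = FALSE] - Zmask[, p]
    b <- (v - base) - Zmask[, p] * tot
    WA <- A * w
    phi_head <- solve(crossprod(A, WA), crossprod(WA, b))
    vals[e, ] <- c(phi_head, tot - sum(phi_head))
  }
  vals
}

#' Top-k features by mean absolute contribution
#'
#' @param summary a `shap_summary` from [shap_contributions()].
#' @param k number of features to report (default 20); if `k` exceeds the
#'   feature count, all are returned with a warning.
#' @param explain_values optional feature matrix (the explained rows) used to
#'   annotate the direction: the sign of the correlation between a feature's
#'   values and its contributions ("high values push positive" when > 0).
#' @return data.frame: rank, feature, mean_abs_contribution, direction.
#' @export
top_features <- function(summary, k = 20, explain_values = NULL) {
  p <- length(summary$feature_names)
  if (k > p) {
    warning("k exceeds the number of features; returning all")
    k <- p
  }
  if (k == 0)
    return(data.frame(rank = integer(), feature = character(),
                      mean_abs_contribution = numeric(),
                      direction = numeric()))
  sel <- summary$order[seq_len(k)]
  dir <- rep(NA_real_, k)
  if (!is.null(explain_values)) {
    ev <- as.matrix(explain_values)
    dir <- vapply(sel, function(i) {
      if (stats::sd(ev[, i]) == 0 || stats::sd(summary$values[, i]) == 0)
        return(0)
      stats::cor(ev[, i], summary$values[, i])
    }, numeric(1))
  }
  data.frame(rank = seq_len(k), feature = summary$feature_names[sel],
             mean_abs_contribution = summary$mean_abs[sel],
             direction = dir, row.names = NULL)
}

#' Beeswarm-style contribution summary plot
#'
#' Plots, for the top-k features (by mean absolute contribution), each
#' sample's signed contribution as a jittered point, colored by the feature
#' value (low = blue, high = red).
#'
#' @param summary a `shap_summary`.
#' @param explain_values the explained feature matrix (for coloring).
#' @param k features to show.
#' @export
shap_summary_plot <- function(summary, explain_values, k = 20) {
  k <- min(k, length(summary$feature_names))
  sel <- rev(summary$order[seq_len(k)])
  ev <- as.matrix(explain_values)
  graphics::plot(NULL, xlim = range(summary$values[, sel], 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "contribution to decision score", ylab = "")
  graphics::axis(2, at = seq_len(k), labels = summary$feature_names[sel],
                 las = 2, cex.axis = 0.7)
  graphics::abline(v = 0, col = "grey")
  pal <- grDevices::colorRampPalette(c("#3b4cc0", "#b40426"))(100)
  for (i in seq_len(k)) {
    fidx <- sel[i]
    v <- ev[, fidx]
    cv <- if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else rep(0.5, length(v))
    graphics::points(summary$values[, fidx],
                     i + stats::runif(length(v), -0.2, 0.2),
                     col = pal[pmax(1, ceiling(cv * 100))], pch = 16, cex = 0.6)
  }
  invisible(NULL)
}
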