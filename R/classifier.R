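#' The default hyperparameter grid
#'
#' The 9 x 5 RBF-SVM search grid: C in 10^-4 .. 10^4 (decades) and gamma in
#' 1, 0.1, 0.01, 0.001, 0.0001.
#'
#' @return list(C = numeric(9), gamma = numeric(5)).
#' @export
hyper_grid <- function() {
  list(C = 10^(-4:4), gamma = 10^(0:-4))
}

#' Min-max rescaling fitted on training rows only
#'
#' Per feature, `x' = (x - min_train) / (max_train - min_train)`. Training
#' columns span \[0, 1\]; values outside the training range (in test data) are
#' not clipped. Zero-range features map to 0 with a warning.
#'
#' @param train numeric matrix used to fit the ranges.
#' @param apply_to optional matrix to transform with the fitted ranges
#'   (defaults to `train`).
#' @return list(train = rescaled train, applied = rescaled apply_to,
#'   min, range).
#' @export
minmax_rescale <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  mn <- apply(train, 2, min)
  rg <- apply(train, 2, max) - mn
  zero <- rg <= 0
  if (any(zero)) {
    warning("zero-range feature(s) mapped to 0: ",
            paste(colnames(train)[zero], collapse = ", "))
    rg[zero] <- 1
  }
  tr <- sweep(sweep(train, 2, mn), 2, rg, "/")
  ap <- sweep(sweep(apply_to, 2, mn), 2, rg, "/")
  tr[, zero] <- 0; ap[, zero] <- 0
  list(train = tr, applied = ap, min = mn, range = rg)
}

#' RBF kernel matrix
#' @noRd
rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(D2, 0))
}

#' Fit an RBF-kernel soft-margin SVM (SMO dual solver)
#'
#' Solves the C-SVM dual by sequential minimal optimization with
#' maximal-violating-pair working-set selection. Class weighting follows the
#' "balanced" convention: each sample's box bound is
#' `C * n / (2 * n_class)`.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels; coerced to 0/1 with `positive` as 1 (the class whose
#'   decision scores are positive).
#' @param C soft-margin cost.
#' @param gamma RBF kernel width.
#' @param positive the positive-class label (default `"patient"` when labels
#'   are characters, else the larger value).
#' @param class_weight `"balanced"` or `"none"`.
#' @param tol KKT violation tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `svm_model`.
#' @export
svm_fit <- function(X, y, C = 1, gamma = 1 / ncol(X), positive = NULL,
                    class_weight = "balanced", tol = 1e-4, max_iter = 100000L) {
  X <- as.matrix(X)
  yy <- encode_labels(y, positive)
  yv <- ifelse(yy$y01 == 1, 1, -1)
  n <- length(yv)
  stopifnot(nrow(X) == n, length(unique(yv)) == 2)
  Cv <- rep(C, n)
  if (identical(class_weight, "balanced")) {
    npos <- sum(yv == 1); nneg <- n - npos
    Cv[yv == 1] <- C * n / (2 * npos)
    Cv[yv == -1] <- C * n / (2 * nneg)
  }
  K <- rbf_kernel(X, X, gamma)
  a <- numeric(n)
  u <- numeric(n)                    # u_k = sum_l a_l y_l K_lk
  E <- u - yv
  for (it in seq_len(max_iter)) {
    up <- (yv == 1 & a < Cv - 1e-12) | (yv == -1 & a > 1e-12)
    lo <- (yv == 1 & a > 1e-12) | (yv == -1 & a < Cv - 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.min(E[up])]
    j <- which(lo)[which.max(E[lo])]
    if (E[j] - E[i] < tol) break
    s <- yv[i] * yv[j]
    if (s < 0) {
      L <- max(0, a[j] - a[i])
      H <- min(Cv[j], Cv[i] + a[j] - a[i])
    } else {
      L <- max(0, a[i] + a[j] - Cv[i])
      H <- min(Cv[j], a[i] + a[j])
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    aj <- a[j] + yv[j] * (E[i] - E[j]) / max(eta, 1e-12)
    aj <- min(max(aj, L), H)
    ai <- a[i] + s * (a[j] - aj)
    dai <- ai - a[i]; daj <- aj - a[j]
    if (abs(dai) + abs(daj) < 1e-15) break
    u <- u + dai * yv[i] * K[, i] + daj * yv[j] * K[, j]
    E <- u - yv
    a[i] <- ai; a[j] <- aj
  }
  up <- (yv == 1 & a < Cv - 1e-12) | (yv == -1 & a > 1e-12)
  lo <- (yv == 1 & a > 1e-12) | (yv == -1 & a < Cv - 1e-12)
  free <- a > 1e-8 & a < Cv - 1e-8
  rho <- if (any(free)) mean(E[free])
         else if (any(up) && any(lo)) (min(E[up]) + max(E[lo])) / 2
         else 0
  sv <- which(a > 1e-10)
  structure(list(sv = X[sv, , drop = FALSE], coef = (a * yv)[sv], rho = rho,
                 gamma = gamma, C = C, labels = yy$labels,
                 positive = yy$positive, n_iter = it),
            class = "svm_model")
}

#' @noRd
encode_labels <- function(y, positive = NULL) {
  if (is.factor(y)) y <- as.character(y)
  labs <- sort(unique(y))
  if (length(labs) != 2) stop("need exactly two classes")
  if (is.null(positive))
    positive <- if ("patient" %in% labs) "patient" else labs[2]
  list(y01 = as.integer(y == positive), labels = labs, positive = positive)
}

#' Decision scores of a fitted SVM
#'
#' `f(x) = sum_j coef_j K(sv_j, x) - rho`; the decision threshold is 0
#' (the margin), positive scores predict the positive class.
#'
#' @param model an `svm_model` from [svm_fit()].
#' @param X feature matrix.
#' @return numeric vector of decision scores.
#' @export
svm_decision <- function(model, X) {
  X <- as.matrix(X)
  as.vector(rbf_kernel(X, model$sv, model$gamma) %*% model$coef) - model$rho
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against 0/1 labels; ties in scores
#' are handled by mid-ranks.
#'
#' @param scores numeric decision scores.
#' @param y01 0/1 labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y01) {
  npos <- sum(y01 == 1); nneg <- sum(y01 == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y01 == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return list of percentages: sensitivity, specificity, ppv, npv,
#'   balanced_accuracy (NA where a denominator is zero).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       ppv = 100 * ppv, npv = 100 * npv,
       balanced_accuracy = 100 * mean(c(sens, spec)))
}

#' Stratified fold assignment
#'
#' @param y01 0/1 labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per sample; every fold holds both classes when
#'   each class has >= k members (asserted).
#' @export
stratified_folds <- function(y01, k, seed = 1L) {
  fold <- integer(length(y01))
  with_seed(seed, {
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified train/test split plan
#'
#' @param y01 0/1 labels.
#' @param ratio training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list(train, test) index vectors; per-class proportions preserved
#'   within one subject.
#' @export
split_plan <- function(y01, ratio = 0.8, seed = 1L) {
  train <- integer()
  with_seed(seed, {
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      train <- c(train, idx[seq_len(round(ratio * length(idx)))])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y01), train),
       ratio = ratio, seed = seed)
}

#' Nested grid search for (C, gamma)
#'
#' Stratified k-fold cross-validation inside the training data: for every
#' grid point the mean validation AUC of a balanced RBF-SVM is computed and
#' the argmax returned; ties break toward smaller C, then smaller gamma.
#'
#' @param X training features (already rescaled).
#' @param y01 0/1 training labels.
#' @param grid a [hyper_grid()]-style list.
#' @param inner_folds folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return list(C, gamma, cv_auc, table = full grid results).
#' @export
nested_grid_search <- function(X, y01, grid = hyper_grid(), inner_folds = 5,
                               seed = 1L) {
  stopifnot(min(table(y01)) >= inner_folds)
  fold <- stratified_folds(y01, inner_folds, derive_seed(seed, "inner_folds"))
  combos <- expand.grid(C = sort(grid$C), gamma = sort(grid$gamma))
  combos$cv_auc <- NA_real_
  for (ci in seq_len(nrow(combos))) {
    aucs <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f; va <- !tr
      stopifnot(length(unique(y01[va])) == 2)
      m <- svm_fit(X[tr, , drop = FALSE], y01[tr], C = combos$C[ci],
                   gamma = combos$gamma[ci], positive = 1)
      aucs[f] <- auc_score(svm_decision(m, X[va, , drop = FALSE]), y01[va])
    }
    combos$cv_auc[ci] <- mean(aucs)
  }
  best <- which.max(combos$cv_auc)  # first max in (C, gamma) ascending order
  list(C = combos$C[best], gamma = combos$gamma[best],
       cv_auc = combos$cv_auc[best], table = combos)
}

#' Evaluate a hyperparameter choice on a feature table
#'
#' Two protocols are reported. `holdout`: the model is fitted on the training
#' rows and scored once on the held-out test rows. `repeated_cv`: stratified
#' k-fold cross-validation over all rows, repeated `repeats` times with
#' fresh fold assignments; per-fold threshold metrics (decision threshold 0)
#' and AUC are averaged, with undefined PPV/NPV folds excluded from their
#' averages. All metrics are percentages.
#'
#' @param X full feature matrix (unscaled; scaling is refit per training set).
#' @param y01 0/1 labels.
#' @param C,gamma hyperparameters.
#' @param split a [split_plan()].
#' @param folds,repeats repeated-CV shape (defaults 5 x 100).
#' @param seed RNG seed.
#' @return list(holdout = metrics list, repeated_cv = metrics list,
#'   C, gamma).
#' @export
evaluate_classifier <- function(X, y01, C, gamma, split, folds = 5,
                                repeats = 100, seed = 1L) {
  X <- as.matrix(X)
  sc <- minmax_rescale(X[split$train, , drop = FALSE], X)
  m <- svm_fit(sc$train, y01[split$train], C = C, gamma = gamma, positive = 1)
  ho_scores <- svm_decision(m, sc$applied[split$test, , drop = FALSE])
  holdout <- threshold_metrics(ho_scores, y01[split$test])
  holdout$auc <- 100 * auc_score(ho_scores, y01[split$test])

  acc <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y01, folds, derive_seed(seed, paste0("rep", r)))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y01[!tr])) < 2 || length(unique(y01[tr])) < 2) next
      sc <- minmax_rescale(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      mf <- svm_fit(sc$train, y01[tr], C = C, gamma = gamma, positive = 1)
      s <- svm_decision(mf, sc$applied)
      mm <- threshold_metrics(s, y01[!tr])
      mm$auc <- 100 * auc_score(s, y01[!tr])
      acc[[length(acc) + 1]] <- mm
    }
  }
  rep_cv <- sapply(c("auc", "balanced_accuracy", "sensitivity", "specificity",
                     "ppv", "npv"),
                   function(k) mean(unlist(lapply(acc, `[[`, k)), na.rm = TRUE),
                   simplify = FALSE)
  list(holdout = holdout, repeated_cv = rep_cv, C = C, gamma = gamma,
       n_cv_folds = length(acc))
}

#' @noRd
threshold_metrics <- function(scores, y01) {
  pred <- as.integer(scores > 0)
  confusion_metrics(tp = sum(pred == 1 & y01 == 1),
                    fn = sum(pred == 0 & y01 == 1),
                    tn = sum(pred == 0 & y01 == 0),
                    fp = sum(pred == 1 & y01 == 0))
}

#' Run the full classification pipeline for one feature family
#'
#' Selects the feature columns of the requested family (a single metric or
#' network, or the concatenation of a family), performs the stratified 80:20
#' split, min-max rescaling fitted on the training rows, nested grid search,
#' and both evaluation protocols.
#'
#' @param features a feature data.frame from [extract_features()] (columns
#'   `<metric>@<label>` plus subject metadata).
#' @param family `"single:<metric>"` (prefix match on the part before `@`),
#'   or `"combined"` using `members` as the metric set.
#' @param members character vector of metric names for a combined family
#'   (defaults to all feature prefixes present).
#' @param seed master seed for split, folds and search.
#' @param ratio training fraction.
#' @param inner_folds,folds,repeats CV shape.
#' @return a `classifier_report`: list(family, features, C, gamma, cv_auc,
#'   holdout, repeated_cv, split).
#' @export
run_model_family <- function(features, family, members = NULL, seed = 1L,
                             ratio = 0.8, inner_folds = 5, folds = 5,
                             repeats = 100) {
  fcols <- grep("@", names(features), value = TRUE)
  prefixes <- sub("@.*", "", fcols)
  if (startsWith(family, "single:")) {
    want <- sub("^single:", "", family)
    cols <- fcols[prefixes == want]
    if (!length(cols))
      stop(sprintf("unknown family '%s'; available: %s", family,
                   paste(unique(prefixes), collapse = ", ")))
  } else if (family == "combined") {
    if (is.null(members)) members <- unique(prefixes)
    cols <- fcols[prefixes %in% members]
    if (!length(cols)) stop("no features for the requested combined family")
  } else stop(sprintf("unknown family '%s'; use 'single:<metric>' or 'combined'",
                      family))
  X <- as.matrix(features[, cols, drop = FALSE])
  y01 <- encode_labels(features$group)$y01
  split <- split_plan(y01, ratio, derive_seed(seed, "split"))
  sc <- minmax_rescale(X[split$train, , drop = FALSE])
  gs <- nested_grid_search(sc$train, y01[split$train], inner_folds = inner_folds,
                           seed = derive_seed(seed, "search"))
  ev <- evaluate_classifier(X, y01, gs$C, gs$gamma, split, folds = folds,
                            repeats = repeats, seed = derive_seed(seed, "eval"))
  structure(list(family = family, features = cols, C = gs$C, gamma = gs$gamma,
                 cv_auc = gs$cv_auc, holdout = ev$holdout,
                 repeated_cv = ev$repeated_cv, split = split),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report [%s]: C=%g gamma=%g (inner CV AUC %.3f)\n",
              x$family, x$C, x$gamma, x$cv_auc))
  f <- function(m) sprintf(
    "AUC %.1f%%  B-ACC %.1f%%  sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%",
    m$auc, m$balanced_accuracy, m$sensitivity, m$specificity, m$ppv, m$npv)
  cat("  holdout:     ", f(x$holdout), "\n")
  cat("  repeated CV: ", f(x$repeated_cv), "\n")
  invisible(x)
}
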