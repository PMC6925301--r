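# The four classifier back-ends behind one train/predict contract:
# LDA (MASS), random forest (randomForest, CART trees), and linear/radial
# SVMs (e1071) with power-of-two hyperparameter grids tuned by inner
# stratified cross-validation.

#' Specify a classifier and its tuning grid
#'
#' @param method One of `"lda"`, `"rf"`, `"svm_linear"`, `"svm_radial"`.
#' @param cost_grid SVM cost grid (default `2^(0:4)`).
#' @param gamma_grid Radial-kernel width grid (default `2^(-8:0)`).
#' @param mtry Features tried at each random-forest split; `NULL` means
#'   `p`, the number of traits the model is fit on (bagged trees).
#' @param n_trees Random-forest ensemble size (default 500).
#' @param tune_folds Inner stratified CV folds for grid search
#'   (default 5).
#' @param standardize Z-score traits with training statistics before SVM
#'   training (default `TRUE`; ignored by LDA and RF, which are
#'   scale-equivariant).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(method = c("lda", "rf", "svm_linear", "svm_radial"),
                            cost_grid = 2^(0:4), gamma_grid = 2^(-8:0),
                            mtry = NULL, n_trees = 500L, tune_folds = 5L,
                            standardize = TRUE) {
  method <- match.arg(method)
  if (method %in% c("svm_linear", "svm_radial") &&
      (length(cost_grid) < 1 || any(cost_grid <= 0))) {
    abort("`cost_grid` must be a non-empty set of positive costs.",
          class = "traitrank_config_error")
  }
  if (method == "svm_radial" &&
      (length(gamma_grid) < 1 || any(gamma_grid <= 0))) {
    abort("`gamma_grid` must be a non-empty set of positive widths.",
          class = "traitrank_config_error")
  }
  if (!is_scalar_number(n_trees) || n_trees < 1) {
    abort("`n_trees` must be >= 1.", class = "traitrank_config_error")
  }
  structure(list(method = method, cost_grid = sort(cost_grid),
                 gamma_grid = sort(gamma_grid), mtry = mtry,
                 n_trees = as.integer(n_trees),
                 tune_folds = as.integer(tune_folds),
                 standardize = standardize),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  grid <- switch(x$method,
    lda = "no tuning",
    rf = sprintf("mtry = %s, %d trees",
                 if (is.null(x$mtry)) "p" else x$mtry, x$n_trees),
    svm_linear = sprintf("C grid {%s}", toString(format(x$cost_grid))),
    svm_radial = sprintf("C grid {%s} x gamma grid of %d",
                         toString(format(x$cost_grid)), length(x$gamma_grid)))
  cat(sprintf("<classifier_spec: %s (%s)>\n", x$method, grid))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so fold class counts differ by at most one.
stratified_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    ids[rows] <- rep_len(seq_len(k), length(rows))
  }
  ids
}

#' Tune hyperparameters by inner stratified cross-validation
#'
#' Evaluates each grid point by `tune_folds`-fold stratified CV on the
#' training data only and returns the setting with the highest mean inner
#' accuracy; ties break toward the smaller cost, then the smaller gamma.
#' LDA needs no tuning and returns an empty setting, as does RF (whose
#' `mtry` is fixed at `p`) and a singleton SVM grid.
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric training matrix.
#' @param y Binary factor labels.
#' @param seed Seed for the inner fold shuffle.
#' @return Named list of chosen hyperparameters (possibly empty).
#' @export
tune_hyperparameters <- function(spec, X, y, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- check_binary_labels(y)
  if (spec$method == "lda") return(list())
  if (spec$method == "rf") {
    return(list(mtry = spec$mtry %||% ncol(X)))
  }
  grid <- if (spec$method == "svm_linear") {
    tibble::tibble(cost = spec$cost_grid)
  } else {
    tidyr::expand_grid(cost = spec$cost_grid, gamma = spec$gamma_grid)
  }
  if (nrow(grid) == 1) return(as.list(grid))
  k <- min(spec$tune_folds, min(table(y)))
  if (k < 2) {
    # too few samples per class for inner CV: fall back to the smallest grid point
    return(as.list(grid[1, ]))
  }
  folds <- with_seed_(seed, stratified_fold_ids(y, k))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- e1071::svm(
        x = X[tr, , drop = FALSE], y = y[tr],
        kernel = if (spec$method == "svm_linear") "linear" else "radial",
        cost = grid$cost[i],
        gamma = if (spec$method == "svm_radial") grid$gamma[i]
                else 1 / ncol(X),
        scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  # ties toward smaller cost then smaller gamma: grid is sorted that way
  as.list(grid[which.max(acc), ])
}

#' Fit a classifier on a trait table
#'
#' Tunes (where the method has a grid), then fits on all rows of `data`.
#' SVM traits are z-scored with training statistics when
#' `spec$standardize` is set; predictions align new tables to the
#' training trait list by name, so column order never matters.
#'
#' @param spec A [classifier_spec()].
#' @param data Trait table with binary `label` and >= 2 samples per
#'   class.
#' @param label,traits,meta Column selection, see [trait_cols()].
#' @param seed Seed covering the inner-CV shuffle and RF randomness.
#' @return A `trait_model`.
#' @export
fit_classifier <- function(spec, data, label = "label", traits = NULL,
                           meta = character(), seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  traits <- trait_cols(data, traits, meta)
  y <- check_binary_labels(data[[label]])
  if (min(table(y)) < 2) {
    abort("Need at least 2 samples per class to fit.",
          class = "traitrank_label_error")
  }
  X <- trait_matrix(data, traits)
  if (!all(is.finite(X))) {
    abort("Non-finite values in the trait matrix; preprocess first.",
          class = "traitrank_data_error")
  }
  center <- scale_ <- NULL
  if (spec$standardize && spec$method %in% c("svm_linear", "svm_radial")) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ == 0] <- 1
    X <- scale(X, center = center, scale = scale_)
  }
  if (spec$method == "lda" && ncol(X) >= nrow(X)) {
    warn(sprintf("LDA with p = %d >= n = %d: expect classical degradation.",
                 ncol(X), nrow(X)))
  }
  t0 <- cpu_seconds()
  chosen <- tune_hyperparameters(spec, X, y,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed, "tune"))
  fit <- with_seed_(if (is.null(seed)) NULL else derive_seed(seed, "fit"),
    switch(spec$method,
      lda = MASS::lda(X, grouping = y, prior = c(0.5, 0.5)),
      rf = randomForest::randomForest(
        x = X, y = y, ntree = spec$n_trees,
        mtry = min(chosen$mtry, ncol(X))),
      svm_linear = e1071::svm(x = X, y = y, kernel = "linear",
                              cost = chosen$cost, scale = FALSE),
      svm_radial = e1071::svm(x = X, y = y, kernel = "radial",
                              cost = chosen$cost, gamma = chosen$gamma,
                              scale = FALSE)))
  structure(list(spec = spec, fit = fit, traits = traits,
                 hyperparameters = chosen,
                 center = center, scale = scale_,
                 levels = levels(y),
                 train_seconds = cpu_seconds() - t0),
            class = "trait_model")
}

#' Predict class labels from a fitted trait model
#'
#' @param object A `trait_model`.
#' @param newdata Trait table (or data frame) containing every training
#'   trait; extra columns are ignored and column order is irrelevant.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  missing <- setdiff(object$traits, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing trait column(s) required by the model: ",
                 toString(missing)),
          class = "traitrank_schema_error")
  }
  X <- trait_matrix(newdata, object$traits)
  if (!is.null(object$center)) {
    X <- scale(X, center = object$center, scale = object$scale)
  }
  pred <- switch(object$spec$method,
    lda = predict(object$fit, X)$class,
    rf = predict(object$fit, X),
    svm_linear = predict(object$fit, X),
    svm_radial = predict(object$fit, X))
  factor(as.character(pred), levels = object$levels)
}

#' @export
print.trait_model <- function(x, ...) {
  hp <- if (length(x$hyperparameters) == 0) "none" else
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = " = ", collapse = ", ")
  cat(sprintf("<trait_model: %s on %d traits; hyperparameters: %s>\n",
              x$spec$method, length(x$traits), hp))
  invisible(x)
}

#' @describeIn fit_classifier One-row model summary.
#' @param x A `trait_model`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.trait_model <- function(x, ...) {
  tibble::tibble(
    method = x$spec$method,
    n_traits = length(x$traits),
    cost = x$hyperparameters$cost %||% NA_real_,
    gamma = x$hyperparameters$gamma %||% NA_real_,
    mtry = x$hyperparameters$mtry %||% NA_integer_,
    train_seconds = x$train_seconds)
}
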