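# Phase (b): trait ranking by linear SVM recursive feature elimination.
# The ranking criterion for trait i is the squared weight w_i^2 of the
# soft-margin linear SVM trained on the surviving traits; the trait with
# the smallest criterion is eliminated each round, and the elimination
# order, reversed, is the trait ranking.

#' Linear SVM weight vector
#'
#' Trains a soft-margin linear SVM (cost `C`) and returns the primal
#' weight vector `w = sum_t alpha_t y_t x_t` over the support vectors,
#' one entry per column of `X`. The solver tolerance is kept tight so the
#' weights, and hence elimination orders, are deterministic for a given
#' input.
#'
#' @param X Numeric matrix, samples x traits.
#' @param y Binary labels (factor or coercible), both classes present.
#' @param C Soft-margin cost, `> 0`.
#' @param tolerance Termination tolerance of the underlying solver.
#' @return Named numeric weight vector of length `ncol(X)`.
#' @export
linear_svm_weights <- function(X, y, C = 1, tolerance = 1e-6) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) {
    abort("Non-finite values in the trait matrix.",
          class = "traitrank_data_error")
  }
  if (!is_scalar_number(C) || C <= 0) {
    abort("`C` must be > 0.", class = "traitrank_config_error")
  }
  y <- check_binary_labels(y)
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(X)
  w
}

#' Rank traits by SVM recursive feature elimination
#'
#' Iteratively trains a linear SVM on the surviving traits, scores each
#' trait by its squared weight `R_i = w_i^2`, eliminates the trait(s)
#' with the smallest criterion, and prepends them to the ranking, until
#' one trait survives (which takes rank 1 without a degenerate final
#' fit). Ties at the minimum criterion eliminate the earliest column
#' first, so duplicated or all-zero traits are handled deterministically.
#'
#' Traits are z-scored (using the statistics of the data given) before
#' training by default, making the ranking invariant to per-trait affine
#' rescaling; without standardization the squared-weight criterion is
#' unit-dependent.
#'
#' @param data Trait table with binary `label`.
#' @param C Soft-margin cost used for every elimination round
#'   (default 1).
#' @param step_size Traits eliminated per round (default 1, the classic
#'   procedure). Larger steps trade ranking resolution for speed; traits
#'   removed together are ordered by ascending criterion.
#' @param standardize Z-score traits before training (default `TRUE`).
#' @param label Label column name.
#' @param traits,meta See [trait_cols()].
#' @param tolerance Passed to [linear_svm_weights()].
#' @return An `rfe_ranking` object: list with `ranking` (tibble of
#'   `rank`, `trait`, `criterion`, `iteration`), `elimination_order`
#'   (worst trait first), `criteria_history` (one tibble row per
#'   iteration x surviving trait), `C`, `step_size`, `standardized`.
#' @export
svm_rfe <- function(data, C = 1, step_size = 1L, standardize = TRUE,
                    label = "label", traits = NULL, meta = character(),
                    tolerance = 1e-6) {
  traits <- trait_cols(data, traits, meta)
  if (length(traits) < 1) {
    abort("No trait columns to rank.", class = "traitrank_schema_error")
  }
  if (!is_scalar_number(step_size) || step_size < 1) {
    abort("`step_size` must be a positive integer.",
          class = "traitrank_config_error")
  }
  y <- check_binary_labels(data[[label]])
  X <- trait_matrix(data, traits)
  if (!all(is.finite(X))) {
    abort("Non-finite values in the trait matrix; preprocess first.",
          class = "traitrank_data_error")
  }
  if (standardize) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1  # constant trait: centred to 0, weight will be 0
    X <- scale(X, center = TRUE, scale = sds)
  }
  p <- length(traits)
  surviving <- seq_len(p)
  eliminated <- character(0)
  elim_criteria <- numeric(0)
  elim_iteration <- integer(0)
  history <- list()
  iteration <- 0L
  while (length(surviving) > 1) {
    iteration <- iteration + 1L
    w <- linear_svm_weights(X[, surviving, drop = FALSE], y, C = C,
                            tolerance = tolerance)
    crit <- w^2
    history[[iteration]] <- tibble::tibble(
      iteration = iteration, trait = traits[surviving], criterion = crit)
    n_drop <- min(step_size, length(surviving) - 1L)
    # eliminate the n_drop lowest criteria, worst first; ties by column order
    ord <- order(crit, seq_along(crit))
    drop_local <- ord[seq_len(n_drop)]
    eliminated <- c(eliminated, traits[surviving[drop_local]])
    elim_criteria <- c(elim_criteria, crit[drop_local])
    elim_iteration <- c(elim_iteration, rep(iteration, n_drop))
    surviving <- surviving[-drop_local]
  }
  # survivor takes rank 1; a final one-trait fit would be degenerate
  eliminated <- c(eliminated, traits[surviving])
  elim_criteria <- c(elim_criteria, NA_real_)
  elim_iteration <- c(elim_iteration, NA_integer_)
  ranked <- rev(eliminated)
  stopifnot(setequal(ranked, traits), !anyDuplicated(ranked))
  ranking <- tibble::tibble(
    rank = seq_len(p), trait = ranked,
    criterion = rev(elim_criteria), iteration = rev(elim_iteration))
  structure(list(ranking = ranking,
                 elimination_order = eliminated[seq_len(p)],
                 criteria_history = dplyr::bind_rows(history),
                 C = C, step_size = as.integer(step_size),
                 standardized = standardize),
            class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  p <- nrow(x$ranking)
  cat(sprintf("SVM-RFE ranking of %d traits (C = %g, step = %d, %s)\n",
              p, x$C, x$step_size,
              if (x$standardized) "standardized" else "raw scale"))
  top <- head(x$ranking$trait, 5)
  cat("  top:", toString(top), if (p > 5) "..." else "", "\n")
  invisible(x)
}

#' @describeIn svm_rfe Tidy the ranking: one row per trait with its rank,
#'   elimination iteration, and criterion at elimination.
#' @param x An `rfe_ranking`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rfe_ranking <- function(x, ...) x$ranking

#' Select the top-ranked traits
#'
#' Returns the first `k` traits of a ranking, or the top fraction
#' (`k = ceiling(fraction * p)`, so 10% of 25 traits selects 3).
#'
#' @param ranking An `rfe_ranking`.
#' @param k Integer count in `[1, p]`.
#' @param fraction Fraction in `(0, 1]`; exactly one of `k`/`fraction`
#'   must be given.
#' @return Character vector of trait names, best first.
#' @export
select_top <- function(ranking, k = NULL, fraction = NULL) {
  stopifnot(inherits(ranking, "rfe_ranking"))
  p <- nrow(ranking$ranking)
  if (is.null(k) == is.null(fraction)) {
    abort("Give exactly one of `k` or `fraction`.",
          class = "traitrank_config_error")
  }
  if (!is.null(fraction)) {
    if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
      abort("`fraction` must lie in (0, 1].", class = "traitrank_config_error")
    }
    k <- ceiling(fraction * p)
  }
  if (!is_scalar_number(k) || k < 1 || k > p || k != round(k)) {
    abort(sprintf("`k` must be an integer in [1, %d].", p),
          class = "traitrank_config_error")
  }
  ranking$ranking$trait[seq_len(k)]
}

#' @describeIn svm_rfe Plot the squared-weight criterion of each trait
#'   across elimination rounds.
#' @param object An `rfe_ranking`.
#' @exportS3Method ggplot2::autoplot
autoplot.rfe_ranking <- function(object, ...) {
  ggplot2::ggplot(object$criteria_history,
                  ggplot2::aes(x = .data$iteration, y = .data$criterion,
                               group = .data$trait, colour = .data$trait)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = nrow(object$ranking) <= 12) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Elimination round", y = expression(w[i]^2),
                  title = "SVM-RFE ranking criteria across rounds") +
    ggplot2::theme_minimal()
}

#' Write a ranking to CSV (and optionally its history to JSON)
#'
#' @param ranking An `rfe_ranking`.
#' @param path Output CSV path (`rank`, `trait`, `iteration`,
#'   `criterion`).
#' @param history_path Optional JSON path for the full criteria history.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, history_path = NULL) {
  readr::write_csv(ranking$ranking[c("rank", "trait", "iteration", "criterion")],
                   path, progress = FALSE)
  if (!is.null(history_path)) {
    jsonlite::write_json(ranking$criteria_history, history_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
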