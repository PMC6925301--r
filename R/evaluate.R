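# The experiment harness: repeated stratified k-fold cross-validation of
# the classifiers over top-ranked trait subsets, and the method x
# rank-fraction accuracy grids the benchmark reports.
#
# Two ranking protocols are supported. rank_inside_fold re-ranks traits on
# every training fold, so test rows never touch ranking, tuning, or
# standardization statistics. rank_once ranks a single time on the full
# table before CV -- the protocol many published studies describe -- which
# leaks test information into the trait subset and typically inflates
# accuracy. The default is the sound one.

#' Cross-validation protocol
#'
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated partitions (default 10; the
#'   benchmark-faithful value is 100).
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @param rank_mode `"rank_inside_fold"` (default; ranking refit on every
#'   training fold) or `"rank_once"` (one ranking of the full table,
#'   reused everywhere -- leaks, provided for comparison).
#' @param seed Integer seed; every fold shuffle and model fit derives its
#'   stream from it.
#' @return A `cv_protocol`.
#' @export
cv_protocol <- function(k = 10L, repeats = 10L, stratified = TRUE,
                        rank_mode = c("rank_inside_fold", "rank_once"),
                        seed = 1L) {
  rank_mode <- match.arg(rank_mode)
  if (!is_scalar_number(k) || k < 2) {
    abort("`k` must be >= 2.", class = "traitrank_protocol_error")
  }
  if (!is_scalar_number(repeats) || repeats < 1) {
    abort("`repeats` must be >= 1.", class = "traitrank_protocol_error")
  }
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = stratified, rank_mode = rank_mode,
                 seed = as.integer(seed)),
            class = "cv_protocol")
}

#' Fold assignments of a protocol
#'
#' Deterministically reproduces the fold partition used by
#' [repeated_cv()] for given labels: per repeat, a stratified (or plain)
#' shuffle assigns each sample to one test fold, so folds partition the
#' sample set exactly.
#'
#' @param y Label vector.
#' @param protocol A [cv_protocol()].
#' @return Tibble with columns `rep`, `fold`, `row`.
#' @export
cv_folds <- function(y, protocol) {
  y <- check_binary_labels(y)
  if (protocol$stratified && protocol$k > min(table(y))) {
    abort(sprintf(
      "Stratified %d-fold CV impossible: smallest class has %d samples.",
      protocol$k, min(table(y))),
      class = "traitrank_protocol_error")
  }
  purrr::map_dfr(seq_len(protocol$repeats), function(r) {
    ids <- with_seed_(derive_seed(protocol$seed, paste0("folds-", r)), {
      if (protocol$stratified) stratified_fold_ids(y, protocol$k)
      else rep_len(seq_len(protocol$k), length(y))[sample.int(length(y))]
    })
    tibble::tibble(rep = r, fold = ids, row = seq_along(y))
  })
}

# Internal: rankings for every (rep, fold) training partition, plus the
# wall-clock seconds each took. Shared across sweep cells.
fold_rankings <- function(data, folds, protocol, label, traits, meta,
                          rfe_C, rfe_step) {
  out <- list()
  for (r in unique(folds$rep)) {
    out[[r]] <- list()
    for (f in seq_len(protocol$k)) {
      train_rows <- folds$row[folds$rep == r & folds$fold != f]
      t0 <- cpu_seconds()
      rk <- svm_rfe(data[train_rows, ], C = rfe_C, step_size = rfe_step,
                    label = label, traits = traits, meta = meta)
      out[[r]][[f]] <- list(ranking = rk,
                            seconds = cpu_seconds() - t0)
    }
  }
  out
}

#' Repeated stratified cross-validation of one classifier
#'
#' For each repeat a fresh seeded stratified partition is drawn; per fold
#' the trait subset is determined (see below), the classifier is tuned and
#' fit on the training rows only, and accuracy is measured on the test
#' fold. The summary accuracy is the mean over repeats of per-repeat mean
#' fold accuracy; its standard error is across repeats.
#'
#' Trait subset per fold:
#' * `traits` given -- that fixed subset, no ranking;
#' * `fraction` / `k_top` given -- the top of an SVM-RFE ranking, refit on
#'   the training fold (`rank_inside_fold`) or computed once on the full
#'   table (`rank_once`);
#' * neither, or `fraction = 1` -- all traits, ranking bypassed.
#'
#' @param data Trait table with binary `label`.
#' @param spec A [classifier_spec()].
#' @param protocol A [cv_protocol()].
#' @param fraction Top fraction of ranked traits in `(0, 1]`.
#' @param k_top Top count of ranked traits (alternative to `fraction`).
#' @param traits Fixed trait subset (overrides ranking).
#' @param label,meta Column selection.
#' @param rfe_C,rfe_step SVM-RFE parameters, see [svm_rfe()].
#' @param .folds,.rankings Precomputed caches used by the sweep drivers;
#'   leave `NULL` in direct calls.
#' @return A `cv_result`: list with `folds` (per-(rep, fold) tibble:
#'   `rep`, `fold`, `accuracy`, `n_test`, `k_traits`, `rank_seconds`,
#'   `model_seconds`), `mean_accuracy`, `se`, `method`, and the subset
#'   directive used.
#' @export
repeated_cv <- function(data, spec, protocol, fraction = NULL, k_top = NULL,
                        traits = NULL, label = "label", meta = character(),
                        rfe_C = 1, rfe_step = 1L,
                        .folds = NULL, .rankings = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(protocol, "cv_protocol"))
  all_traits <- trait_cols(data, NULL, meta)
  y <- check_binary_labels(data[[label]])
  if (!is.null(fraction) && fraction >= 1) fraction <- NULL  # bypass
  needs_ranking <- is.null(traits) && (!is.null(fraction) || !is.null(k_top))
  folds <- .folds %||% cv_folds(y, protocol)
  once_ranking <- NULL
  once_seconds <- 0
  if (needs_ranking && protocol$rank_mode == "rank_once" && is.null(.rankings)) {
    t0 <- cpu_seconds()
    once_ranking <- svm_rfe(data, C = rfe_C, step_size = rfe_step,
                            label = label, meta = meta)
    once_seconds <- cpu_seconds() - t0
  }
  if (needs_ranking && protocol$rank_mode == "rank_inside_fold" &&
      is.null(.rankings)) {
    .rankings <- fold_rankings(data, folds, protocol, label, NULL, meta,
                               rfe_C, rfe_step)
  }
  rows <- purrr::map_dfr(seq_len(protocol$repeats), function(r) {
    purrr::map_dfr(seq_len(protocol$k), function(f) {
      test_rows <- folds$row[folds$rep == r & folds$fold == f]
      train_rows <- folds$row[folds$rep == r & folds$fold != f]
      rank_seconds <- 0
      subset <- traits %||% all_traits
      if (needs_ranking) {
        if (protocol$rank_mode == "rank_inside_fold") {
          rk <- .rankings[[r]][[f]]
          rank_seconds <- rk$seconds
          rk <- rk$ranking
        } else {
          rk <- once_ranking
          rank_seconds <- once_seconds
        }
        subset <- select_top(rk, k = k_top, fraction = fraction)
      }
      t0 <- cpu_seconds()
      model <- fit_classifier(spec, data[train_rows, ], label = label,
                              traits = subset, meta = meta,
                              seed = derive_seed(protocol$seed,
                                paste("fit", spec$method, r, f,
                                      length(subset))))
      pred <- predict(model, data[test_rows, ])
      model_seconds <- cpu_seconds() - t0
      tibble::tibble(rep = r, fold = f,
                     accuracy = mean(pred == y[test_rows]),
                     n_test = length(test_rows),
                     k_traits = length(subset),
                     rank_seconds = rank_seconds,
                     model_seconds = model_seconds)
    })
  })
  per_rep <- dplyr::summarise(dplyr::group_by(rows, .data$rep),
                              acc = mean(.data$accuracy), .groups = "drop")
  structure(list(folds = rows,
                 mean_accuracy = mean(per_rep$acc),
                 se = if (nrow(per_rep) > 1)
                        sd(per_rep$acc) / sqrt(nrow(per_rep)) else 0,
                 method = spec$method,
                 fraction = fraction, k_top = k_top,
                 fixed_traits = traits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result: %s, %d repeats x %d folds, mean accuracy %.4f (SE %.4f)>\n",
    x$method, max(x$folds$rep), max(x$folds$fold), x$mean_accuracy, x$se))
  invisible(x)
}

#' @describeIn repeated_cv Per-fold accuracy rows.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$folds

#' @describeIn repeated_cv One-row summary (mean accuracy, SE, timing).
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 mean_accuracy = x$mean_accuracy, se = x$se,
                 repeats = max(x$folds$rep), k = max(x$folds$fold),
                 mean_rank_seconds = mean(x$folds$rank_seconds),
                 mean_model_seconds = mean(x$folds$model_seconds))
}

# Shared driver behind fraction_sweep() and count_sweep().
sweep_cells <- function(data, specs, cells, protocol, label, meta,
                        rfe_C, rfe_step) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, function(s) s$method, character(1))
  y <- check_binary_labels(data[[label]])
  folds <- cv_folds(y, protocol)
  needs_ranking <- any(!vapply(cells, function(c)
    is.null(c$fraction) && is.null(c$k_top), logical(1)))
  rankings <- NULL
  if (needs_ranking && protocol$rank_mode == "rank_inside_fold") {
    rankings <- fold_rankings(data, folds, protocol, label, NULL, meta,
                              rfe_C, rfe_step)
  }
  results <- list()
  grid <- purrr::map_dfr(names(specs), function(m) {
    purrr::map_dfr(cells, function(cell) {
      res <- tryCatch(
        repeated_cv(data, specs[[m]], protocol,
                    fraction = cell$fraction, k_top = cell$k_top,
                    label = label, meta = meta,
                    rfe_C = rfe_C, rfe_step = rfe_step,
                    .folds = folds, .rankings = rankings),
        error = function(e) e)
      key <- paste(m, cell$label, sep = "@")
      results[[key]] <<- res
      if (inherits(res, "error")) {
        tibble::tibble(method = m, at = cell$label,
                       k_traits = NA_integer_,
                       mean_accuracy = NA_real_, se = NA_real_,
                       mean_rank_seconds = NA_real_,
                       mean_model_seconds = NA_real_,
                       error = conditionMessage(res))
      } else {
        tibble::tibble(method = m, at = cell$label,
                       k_traits = res$folds$k_traits[1],
                       mean_accuracy = res$mean_accuracy, se = res$se,
                       mean_rank_seconds = mean(res$folds$rank_seconds),
                       mean_model_seconds = mean(res$folds$model_seconds),
                       error = NA_character_)
      }
    })
  })
  structure(grid, class = c("accuracy_table", class(grid)),
            cells = results, protocol = protocol)
}

#' Sweep classifiers over top-ranked trait fractions
#'
#' Runs [repeated_cv()] for every (method, fraction) cell. The
#' all-features column (`fraction = 1`) bypasses ranking entirely. Cells
#' share fold partitions and per-fold rankings, so the grid is internally
#' consistent; a failing cell is marked in its `error` column and the
#' remaining cells still run.
#'
#' @param data Trait table with binary `label`.
#' @param specs A [classifier_spec()] or list of them.
#' @param fractions Numeric fractions in `(0, 1]`
#'   (default `c(.1, .2, .3, .4, .5, 1)`).
#' @param protocol A [cv_protocol()].
#' @param label,meta Column selection.
#' @param rfe_C,rfe_step SVM-RFE parameters.
#' @return An `accuracy_table`: a tibble with one row per cell (`method`,
#'   `at`, `k_traits`, `mean_accuracy`, `se`, `mean_rank_seconds`,
#'   `mean_model_seconds`, `error`), with per-cell `cv_result`s in
#'   `attr(, "cells")`.
#' @export
fraction_sweep <- function(data, specs,
                           fractions = c(0.1, 0.2, 0.3, 0.4, 0.5, 1),
                           protocol = cv_protocol(),
                           label = "label", meta = character(),
                           rfe_C = 1, rfe_step = 1L) {
  if (length(fractions) < 1 || any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must be non-empty, each in (0, 1].",
          class = "traitrank_config_error")
  }
  cells <- purrr::map(fractions, function(f) list(
    fraction = if (f < 1) f else NULL,
    k_top = NULL,
    label = sprintf("%d%%", round(100 * f))))
  sweep_cells(data, specs, cells, protocol, label, meta, rfe_C, rfe_step)
}

#' Sweep classifiers over explicit top-k trait counts
#'
#' As [fraction_sweep()], but with explicit counts of top-ranked traits
#' (the layout used when features are added sequentially, e.g.
#' `c(2, 4, 6, 8, 10)`). A count equal to the total number of traits is
#' the all-features cell.
#'
#' @inheritParams fraction_sweep
#' @param counts Integer counts within `[1, p]`.
#' @return An `accuracy_table` (see [fraction_sweep()]).
#' @export
count_sweep <- function(data, specs, counts = c(2, 4, 6, 8, 10),
                        protocol = cv_protocol(),
                        label = "label", meta = character(),
                        rfe_C = 1, rfe_step = 1L) {
  p <- length(trait_cols(data, NULL, meta))
  if (length(counts) < 1 || any(counts < 1 | counts > p)) {
    abort(sprintf("`counts` must lie in [1, %d].", p),
          class = "traitrank_config_error")
  }
  cells <- purrr::map(as.integer(counts), function(kk) list(
    fraction = NULL,
    k_top = if (kk < p) kk else NULL,  # k = p: all features, no ranking
    label = as.character(kk)))
  sweep_cells(data, specs, cells, protocol, label, meta, rfe_C, rfe_step)
}

#' @describeIn fraction_sweep Tidy the grid: one row per cell, with the
#'   best cell per method flagged (`is_best`).
#' @param x An `accuracy_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.accuracy_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::mutate(dplyr::group_by(out, .data$method),
                is_best = !is.na(.data$mean_accuracy) &
                  .data$mean_accuracy == max(.data$mean_accuracy, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' @describeIn fraction_sweep Plot mean accuracy (with SE ribbons) against
#'   the rank-feature fraction or count, one line per method.
#' @param object An `accuracy_table`.
#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$at <- factor(d$at, levels = unique(d$at))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$at, y = .data$mean_accuracy,
                                  colour = .data$method,
                                  group = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$se,
      ymax = .data$mean_accuracy + .data$se,
      fill = .data$method), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Rank features", y = "Mean CV accuracy",
                  title = "Classifier accuracy over top-ranked trait subsets") +
    ggplot2::theme_minimal()
}

#' Write an accuracy table as TSV
#'
#' Methods x rank-feature grid of `mean (SE)` accuracy cells. Timing
#' columns are deliberately excluded so identical seeds yield
#' byte-identical files.
#'
#' @param x An `accuracy_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_accuracy_tsv <- function(x, path) {
  d <- tibble::as_tibble(x)
  d$cell <- sprintf("%.4f (%.4f)", d$mean_accuracy, d$se)
  wide <- tidyr::pivot_wider(d[c("method", "at", "cell")],
                             names_from = "at", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
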