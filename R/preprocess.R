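# Phase (a) of the workflow: filtering replicated trait tables before any
# ranking or classification. Filters only remove or mask rows, columns, or
# cells -- a retained numeric value is never modified.

new_trace <- function(stage, before, after, removed) {
  structure(list(stage = stage,
                 samples_before = before[1], traits_before = before[2],
                 samples_after = after[1], traits_after = after[2],
                 removed = removed),
            class = "filter_trace")
}

removed_tbl <- function(type = character(), id = character(),
                        reason = character(), detail = numeric()) {
  tibble::tibble(type = type, id = id, reason = reason, detail = detail)
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf("<filter_trace: %s>  samples %d -> %d, traits %d -> %d, %d removal(s)\n",
              x$stage, x$samples_before, x$samples_after,
              x$traits_before, x$traits_after, nrow(x$removed)))
  invisible(x)
}

#' Resolve empty (zero-coded) values in image-derived traits
#'
#' Image-export pipelines commonly code missing measurements as `0`.
#' This filter recodes zeros as missing in the designated trait columns
#' and resolves missingness per `policy`: `"drop_sample"` removes rows
#' with any missing trait, `"drop_trait"` removes traits whose missing
#' fraction exceeds `cutoff` (then drops rows still containing missing
#' values), and `"mask"` leaves `NA`s in place.
#'
#' @param data Trait table.
#' @param policy One of `"drop_sample"`, `"drop_trait"`, `"mask"`.
#' @param cutoff Missing-fraction cutoff for `"drop_trait"`.
#' @param zero_as_missing `TRUE` recodes zeros in all trait columns,
#'   `FALSE` in none; a character vector recodes only the named columns
#'   (exempting genuinely zero-valued traits).
#' @param traits,meta See [trait_cols()].
#' @return A list with elements `data` (filtered tibble) and `trace`
#'   (a `filter_trace`).
#' @export
drop_empty_values <- function(data, policy = c("drop_sample", "drop_trait", "mask"),
                              cutoff = 0.5, zero_as_missing = TRUE,
                              traits = NULL, meta = character()) {
  policy <- match.arg(policy)
  traits <- trait_cols(data, traits, meta)
  before <- c(nrow(data), length(traits))
  zero_cols <- if (isTRUE(zero_as_missing)) traits
               else if (isFALSE(zero_as_missing)) character()
               else intersect(zero_as_missing, traits)
  for (tc in zero_cols) {
    data[[tc]][!is.na(data[[tc]]) & data[[tc]] == 0] <- NA_real_
  }
  removed <- removed_tbl()
  if (policy == "drop_trait") {
    miss_frac <- vapply(data[traits], function(v) mean(is.na(v)), numeric(1))
    drop <- traits[miss_frac > cutoff]
    if (length(drop) == length(traits)) {
      abort("All traits exceed the missing-fraction cutoff; nothing left.",
            class = "traitrank_empty_result_error")
    }
    removed <- dplyr::bind_rows(removed, removed_tbl(
      type = rep("trait", length(drop)), id = drop,
      reason = rep("missing_fraction", length(drop)),
      detail = miss_frac[miss_frac > cutoff]))
    data <- data[setdiff(names(data), drop)]
    traits <- setdiff(traits, drop)
  }
  if (policy %in% c("drop_sample", "drop_trait")) {
    keep <- complete.cases(data[traits])
    dropped_ids <- data$sample_id[!keep]
    removed <- dplyr::bind_rows(removed, removed_tbl(
      type = rep("sample", length(dropped_ids)), id = dropped_ids,
      reason = rep("missing_value", length(dropped_ids)),
      detail = rep(NA_real_, length(dropped_ids))))
    data <- data[keep, ]
  }
  list(data = data,
       trace = new_trace("drop_empty_values", before,
                         c(nrow(data), length(traits)), removed))
}

#' Remove outlying cells per replicate group and trait
#'
#' Applies [grubbs_outliers()] or [bonferroni_outliers()] to each
#' (group x trait) vector of repeated measurements and sets flagged cells
#' to missing, preserving the sample's other traits. Missingness is then
#' resolved with the `policy` of [drop_empty_values()].
#'
#' @param data Trait table.
#' @param method `"grubbs"` or `"bonferroni"`.
#' @param alpha Significance level.
#' @param group_by Character vector of metadata columns defining replicate
#'   groups (e.g. genotype and treatment); `NULL` treats all rows as one
#'   group.
#' @param policy Missing-value policy applied after masking
#'   (default `"mask"` keeps all samples).
#' @param traits,meta See [trait_cols()].
#' @return A list with `data`, `trace`, and `report` (the combined
#'   outlier report across groups and traits).
#' @export
remove_outliers <- function(data, method = c("grubbs", "bonferroni"),
                            alpha = 0.05, group_by = NULL,
                            policy = "mask", traits = NULL,
                            meta = character()) {
  method <- match.arg(method)
  meta <- union(meta, group_by %||% character())
  traits <- trait_cols(data, traits, meta)
  before <- c(nrow(data), length(traits))
  group_key <- if (is.null(group_by)) rep("all", nrow(data))
               else do.call(paste, c(data[group_by], sep = ":"))
  test_fun <- if (method == "grubbs") {
    function(v) grubbs_outliers(v, alpha = alpha)
  } else {
    function(v) bonferroni_outliers(v, alpha = alpha)
  }
  reports <- list()
  for (g in unique(group_key)) {
    rows <- which(group_key == g)
    for (tc in traits) {
      v <- data[[tc]][rows]
      rep_g <- tryCatch(
        withCallingHandlers(test_fun(v),
          traitrank_degenerate_input = function(w) {
            invokeRestart("muffleWarning")
          }),
        traitrank_insufficient_data_error = function(e) NULL)
      if (!is.null(rep_g) && nrow(rep_g) > 0) {
        rep_g$group <- g
        rep_g$trait <- tc
        rep_g$sample_id <- data$sample_id[rows[rep_g$index]]
        data[[tc]][rows[rep_g$index]] <- NA_real_
        reports[[length(reports) + 1]] <- rep_g
      }
    }
  }
  report <- if (length(reports)) dplyr::bind_rows(reports) else {
    r <- empty_outlier_report(method, alpha)
    r$group <- character(0); r$trait <- character(0)
    r$sample_id <- character(0)
    r
  }
  resolved <- drop_empty_values(data, policy = policy,
                                zero_as_missing = FALSE,
                                traits = traits, meta = meta)
  removed <- dplyr::bind_rows(
    removed_tbl(type = rep("cell", nrow(report)),
                id = paste0(report$sample_id, "/", report$trait),
                reason = rep(paste0(method, "_outlier"), nrow(report)),
                detail = report$statistic),
    resolved$trace$removed)
  list(data = resolved$data,
       trace = new_trace("remove_outliers", before,
                         c(nrow(resolved$data), length(trait_cols(resolved$data, NULL, meta))),
                         removed),
       report = report)
}

#' Screen traits for reproducibility across replicates
#'
#' A trait measured on replicated plants of the same experimental unit
#' (genotype x treatment) should agree across replicates. For each trait
#' the Pearson correlation between replicate vectors (average of all
#' pairwise replicate correlations when there are more than two) is
#' computed across units; traits with `r < r_min` are removed. Traits with
#' fewer than 3 complete unit pairs are not assessable and are retained
#' with a warning.
#'
#' @param data Trait table with unit and replicate metadata columns.
#' @param unit Column naming the experimental unit.
#' @param replicate Column naming the replicate within unit.
#' @param r_min Minimum Pearson correlation to retain a trait, in `[0, 1]`.
#' @param traits,meta See [trait_cols()].
#' @return A list with `data`, `trace`, and `correlations` (per-trait
#'   tibble of `trait`, `r`, `n_pairs`, `assessable`).
#' @export
reproducibility_filter <- function(data, unit, replicate, r_min = 0.7,
                                   traits = NULL, meta = character()) {
  if (!is_scalar_number(r_min) || r_min < 0 || r_min > 1) {
    abort("`r_min` must lie in [0, 1].", class = "traitrank_config_error")
  }
  meta <- union(meta, c(unit, replicate))
  traits <- trait_cols(data, traits, meta)
  before <- c(nrow(data), length(traits))
  units <- data[[unit]]
  reps <- data[[replicate]]
  rep_levels <- sort(unique(reps))
  cors <- purrr::map_dfr(traits, function(tc) {
    wide <- vapply(rep_levels, function(r) {
      v <- rep(NA_real_, length(unique(units)))
      rows <- reps == r
      agg <- tapply(data[[tc]][rows], units[rows], mean, na.rm = TRUE)
      v[match(names(agg), unique(units))] <- agg
      v
    }, numeric(length(unique(units))))
    pairs <- utils::combn(ncol(wide), 2, simplify = FALSE)
    rs <- purrr::map_dbl(pairs, function(pr) {
      ok <- complete.cases(wide[, pr])
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(cor(wide[ok, pr[1]], wide[ok, pr[2]]))
    })
    n_pairs <- max(vapply(pairs, function(pr) sum(complete.cases(wide[, pr])),
                          integer(1)))
    tibble::tibble(trait = tc, r = mean(rs, na.rm = TRUE),
                   n_pairs = n_pairs,
                   assessable = any(!is.na(rs)))
  })
  if (any(!cors$assessable)) {
    warn(paste0("Trait(s) not assessable for reproducibility (",
                "< 3 complete replicate pairs), retained: ",
                toString(cors$trait[!cors$assessable])),
         class = "traitrank_not_assessable")
  }
  drop <- cors$trait[cors$assessable & !is.na(cors$r) & cors$r < r_min]
  removed <- removed_tbl(type = rep("trait", length(drop)), id = drop,
                         reason = rep("low_reproducibility", length(drop)),
                         detail = cors$r[match(drop, cors$trait)])
  data <- data[setdiff(names(data), drop)]
  list(data = data,
       trace = new_trace("reproducibility_filter", before,
                         c(nrow(data), length(traits) - length(drop)),
                         removed),
       correlations = cors)
}

# VIFs for every column of X: VIF_i = 1 / (1 - R_i^2) from regressing
# column i on the others. Perfect collinearity gives +Inf.
compute_vifs <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(i) {
    fit <- lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    tss <- sum((X[, i] - mean(X[, i]))^2)
    rss <- sum(fit$residuals^2)
    if (tss <= 0) return(1)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise trait removal by variance inflation factor
#'
#' Computes `VIF_i = 1 / (1 - R_i^2)` for every trait (R^2 from
#' regressing trait i on all other surviving traits) and repeatedly
#' removes the trait with the largest VIF while that maximum exceeds
#' `vif_max`. Perfectly collinear traits have infinite VIF and are
#' removable, not an error. Ties go to the earlier trait column, so the
#' procedure is deterministic. Stops when at most 2 traits remain.
#'
#' @param data Trait table with strictly more samples than traits.
#' @param vif_max Maximum tolerated VIF (default 10).
#' @param traits,meta See [trait_cols()].
#' @return A list with `data`, `trace`, and `steps` (tibble of the removal
#'   sequence: `step`, `trait`, `vif`).
#' @export
vif_stepwise <- function(data, vif_max = 10, traits = NULL,
                         meta = character()) {
  traits <- trait_cols(data, traits, meta)
  if (length(traits) < 2) {
    abort("VIF screening needs at least 2 traits.",
          class = "traitrank_config_error")
  }
  if (nrow(data) <= length(traits)) {
    abort(paste0("VIF requires more samples than traits (n = ", nrow(data),
                 ", p = ", length(traits),
                 "); filter traits first (reproducibility or missing-value ",
                 "stages) before VIF screening."),
          class = "traitrank_dimensionality_error")
  }
  X <- trait_matrix(data, traits)
  if (anyNA(X)) {
    abort("VIF screening requires complete data; resolve missing values first.",
          class = "traitrank_data_error")
  }
  before <- c(nrow(data), length(traits))
  surviving <- traits
  steps <- tibble::tibble(step = integer(0), trait = character(0),
                          vif = numeric(0))
  while (length(surviving) > 2) {
    vifs <- compute_vifs(X[, surviving, drop = FALSE])
    if (max(vifs) <= vif_max) break
    worst <- which(vifs == max(vifs))[1]  # tie: earliest trait order
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = nrow(steps) + 1L, trait = surviving[worst], vif = vifs[worst]))
    surviving <- surviving[-worst]
  }
  removed <- removed_tbl(type = rep("trait", nrow(steps)), id = steps$trait,
                         reason = rep("high_vif", nrow(steps)),
                         detail = steps$vif)
  data <- data[setdiff(names(data), steps$trait)]
  list(data = data,
       trace = new_trace("vif_stepwise", before,
                         c(nrow(data), length(surviving)), removed),
       steps = steps)
}

#' The phase-(a) preprocessing pipeline
#'
#' Applies, in fixed order: zero-as-missing resolution, per-group outlier
#' masking, reproducibility screening, and stepwise VIF pruning. Stages
#' are enabled by inclusion in `stages`; the order is a pipeline contract
#' and does not depend on the order given.
#'
#' @param data Trait table.
#' @param stages Subset of
#'   `c("missing", "outliers", "reproducibility", "vif")`.
#' @param policy,cutoff,zero_as_missing Passed to [drop_empty_values()].
#' @param outlier_method,alpha,group_by Passed to [remove_outliers()];
#'   flagged cells are masked and then resolved with `policy`.
#' @param unit,replicate,r_min Passed to [reproducibility_filter()]
#'   (the stage is skipped with a warning when `unit` is `NULL`).
#' @param vif_max Passed to [vif_stepwise()].
#' @param traits,meta See [trait_cols()].
#' @return A `preprocess_result`: list with `data` (the filtered table)
#'   and `traces` (one `filter_trace` per enabled stage).
#' @export
preprocess_traits <- function(data,
                              stages = c("missing", "outliers",
                                         "reproducibility", "vif"),
                              policy = "drop_sample", cutoff = 0.5,
                              zero_as_missing = TRUE,
                              outlier_method = "grubbs", alpha = 0.05,
                              group_by = NULL,
                              unit = NULL, replicate = NULL, r_min = 0.7,
                              vif_max = 10,
                              traits = NULL, meta = character()) {
  if (length(stages) > 0) stages <- match.arg(stages, several.ok = TRUE)
  meta <- union(meta, c(group_by %||% character(), unit %||% character(),
                        replicate %||% character()))
  traces <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      abort(paste0("Preprocessing stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "traitrank_stage_error", parent = e)
    })
    traces[[name]] <<- res$trace
    res$data
  }
  if ("missing" %in% stages) {
    data <- run_stage("missing", function()
      drop_empty_values(data, policy = policy, cutoff = cutoff,
                        zero_as_missing = zero_as_missing,
                        traits = traits, meta = meta))
    traits <- intersect(traits %||% character(0), names(data))
    if (length(traits) == 0) traits <- NULL
  }
  if ("outliers" %in% stages) {
    data <- run_stage("outliers", function()
      remove_outliers(data, method = outlier_method, alpha = alpha,
                      group_by = group_by, policy = policy,
                      traits = traits, meta = meta))
  }
  if ("reproducibility" %in% stages) {
    if (is.null(unit) || is.null(replicate)) {
      warn("Reproducibility stage skipped: no `unit`/`replicate` columns given.")
    } else {
      data <- run_stage("reproducibility", function()
        reproducibility_filter(data, unit = unit, replicate = replicate,
                               r_min = r_min, traits = traits, meta = meta))
      traits <- intersect(traits %||% character(0), names(data))
      if (length(traits) == 0) traits <- NULL
    }
  }
  if ("vif" %in% stages) {
    data <- run_stage("vif", function()
      vif_stepwise(data, vif_max = vif_max, traits = traits, meta = meta))
  }
  structure(list(data = data, traces = traces), class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("Preprocessing result:\n")
  for (tr in x$traces) print(tr)
  cat(sprintf("Final table: %d samples x %d traits\n", nrow(x$data),
              length(trait_cols(x$data))))
  invisible(x)
}

#' @describeIn preprocess_traits Tidy per-stage summary of the traces.
#' @param x A `preprocess_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.preprocess_result <- function(x, ...) {
  purrr::map_dfr(x$traces, function(tr) tibble::tibble(
    stage = tr$stage,
    samples_before = tr$samples_before, samples_after = tr$samples_after,
    traits_before = tr$traits_before, traits_after = tr$traits_after,
    n_removed = nrow(tr$removed)))
}

#' Serialize filter traces to JSON
#'
#' @param result A `preprocess_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(result, path) {
  payload <- purrr::map(result$traces, function(tr) list(
    stage = tr$stage,
    samples_before = tr$samples_before, samples_after = tr$samples_after,
    traits_before = tr$traits_before, traits_after = tr$traits_after,
    removed = tr$removed))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
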