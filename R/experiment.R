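# Top-level experiment runner: config in, artifacts on disk out.
# One global seed expands into per-stage seeds (see derive_seed()), so a
# partial re-run of any stage reproduces exactly.

# A grid is either an explicit numeric vector or a power notation
# list(base, min_exp, max_exp), e.g. base 2 from exponent 0 to 4.
parse_grid <- function(g) {
  if (is.numeric(g)) return(g)
  if (is.list(g) && all(c("base", "min_exp", "max_exp") %in% names(g))) {
    return(g$base^(g$min_exp:g$max_exp))
  }
  abort("A grid must be a numeric vector or {base, min_exp, max_exp}.",
        class = "traitrank_config_error")
}

#' Read and validate a run configuration
#'
#' Parses a YAML run configuration into validated component objects:
#' a [sim_config()] (whose `epsilon` may instead be given as
#' `epsilon_bayes`, the target full-feature Bayes accuracy, solved via
#' [epsilon_for_bayes()]), a list of [classifier_spec()]s, a
#' [cv_protocol()], SVM-RFE settings, and the sweep fractions. Unknown
#' classifier methods or invalid parameters fail here, before any
#' computation.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A `run_config` list: `seed`, `simulation`, `specs`,
#'   `protocol`, `ranking`, `fractions`, `raw` (the original list) and
#'   `hash`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  # NB: exact [[ ]] access throughout -- `$` partial matching would let
  # e.g. `epsilon` silently pick up `epsilon_bayes`.
  seed <- as.integer(raw[["seed"]] %||% 1L)
  s <- raw[["simulation"]]
  if (is.null(s)) {
    abort("Config needs a `simulation` section.",
          class = "traitrank_config_error")
  }
  eps <- s[["epsilon"]]
  if (is.null(eps)) {
    if (is.null(s[["epsilon_bayes"]])) {
      abort("Simulation needs `epsilon` or `epsilon_bayes`.",
            class = "traitrank_config_error")
    }
    eps <- epsilon_for_bayes(s[["epsilon_bayes"]], p = s[["p"]],
                             cov_family = s[["cov_family"]] %||% "compound_symmetry",
                             sigma = s[["sigma"]] %||% 1,
                             rho = s[["rho"]] %||% 0,
                             informative_subset = s[["informative_subset"]])
  }
  sim <- sim_config(
    n1 = s[["n1"]], n2 = s[["n2"]], p = s[["p"]], epsilon = unlist(eps),
    mu1 = s[["mu1"]] %||% 0,
    cov_family = s[["cov_family"]] %||% "compound_symmetry",
    sigma = s[["sigma"]] %||% 1, rho = s[["rho"]] %||% 0,
    informative_subset = s[["informative_subset"]],
    epsilon_policy = s[["epsilon_policy"]] %||% "round_robin",
    seed = derive_seed(seed, "simulate"))
  specs <- purrr::map(raw[["classifiers"]], function(cl) {
    classifier_spec(
      method = cl[["method"]],
      cost_grid = parse_grid(cl[["cost_grid"]] %||% 2^(0:4)),
      gamma_grid = parse_grid(cl[["gamma_grid"]] %||% 2^(-8:0)),
      mtry = cl[["mtry"]], n_trees = cl[["n_trees"]] %||% 500L,
      tune_folds = cl[["tune_folds"]] %||% 5L)
  })
  if (length(specs) == 0) {
    abort("Config needs at least one classifier.",
          class = "traitrank_config_error")
  }
  pr <- raw[["protocol"]] %||% list()
  protocol <- cv_protocol(k = pr[["k"]] %||% 10L,
                          repeats = pr[["repeats"]] %||% 10L,
                          stratified = pr[["stratified"]] %||% TRUE,
                          rank_mode = pr[["rank_mode"]] %||% "rank_inside_fold",
                          seed = derive_seed(seed, "protocol"))
  rk <- raw[["ranking"]] %||% list()
  list(seed = seed, simulation = sim, specs = specs, protocol = protocol,
       ranking = list(C = rk[["C"]] %||% 1,
                      step_size = rk[["step_size"]] %||% 1L),
       fractions = unlist(raw[["fractions"]] %||% c(0.1, 0.2, 0.3, 0.4, 0.5, 1)),
       preprocess = raw[["preprocess"]],
       raw = raw, hash = rlang::hash(raw))
}

#' Run a configured experiment end to end
#'
#' Simulates a trait table, optionally preprocesses it, runs the
#' rank-fraction sweep, and writes all artifacts to `out_dir`:
#' `traits.csv` (the simulated table), `accuracy.tsv` (the methods x
#' fractions grid; byte-identical across runs with the same seed),
#' `cells.json` (per-fold detail and timings), `metadata.json` (seed,
#' config hash, package version), and `log.txt`.
#'
#' @param config Path to a YAML config, or the result of
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param repeats Optional override of the protocol's repeat count.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 on success), the
#'   `accuracy_table`, and `paths` of the artifacts.
#' @export
run_experiment <- function(config, out_dir, repeats = NULL, quiet = FALSE) {
  if (is.character(config) || !("specs" %in% names(config))) {
    config <- read_run_config(config)
  }
  if (!is.null(repeats)) config$protocol$repeats <- as.integer(repeats)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      say(stage, paste0("FAILED: ", conditionMessage(e)))
      abort(paste0("Stage `", stage, "` failed: ", conditionMessage(e)),
            class = "traitrank_stage_error", parent = e)
    })
  }
  say("config", sprintf("hash %s, seed %d, %d classifier(s)",
                        config$hash, config$seed, length(config$specs)))
  data <- run_stage("simulate", {
    d <- simulate_two_class(config$simulation)
    say("simulate", sprintf("%d samples x %d traits (Bayes accuracy %.4f)",
                            nrow(d), config$simulation$p,
                            bayes_accuracy(config$simulation)))
    d
  })
  write_trait_csv(data, file.path(out_dir, "traits.csv"))
  if (isTRUE(config$preprocess$enabled)) {
    data <- run_stage("preprocess", {
      pp <- do.call(preprocess_traits,
                    c(list(data = data),
                      config$preprocess[setdiff(names(config$preprocess),
                                                "enabled")]))
      say("preprocess", sprintf("%d samples x %d traits retained",
                                nrow(pp$data), length(trait_cols(pp$data))))
      write_trace_json(pp, file.path(out_dir, "filter_traces.json"))
      pp$data
    })
  }
  grid <- run_stage("sweep", {
    g <- fraction_sweep(data, config$specs, fractions = config$fractions,
                        protocol = config$protocol,
                        rfe_C = config$ranking$C,
                        rfe_step = config$ranking$step_size)
    for (i in seq_len(nrow(g))) {
      say("sweep", sprintf("%s @ %s: accuracy %.4f (SE %.4f)",
                           g$method[i], g$at[i], g$mean_accuracy[i], g$se[i]))
    }
    g
  })
  paths <- list(
    traits = file.path(out_dir, "traits.csv"),
    accuracy = write_accuracy_tsv(grid, file.path(out_dir, "accuracy.tsv")),
    cells = file.path(out_dir, "cells.json"),
    metadata = file.path(out_dir, "metadata.json"),
    log = log_path)
  cells <- attr(grid, "cells")
  jsonlite::write_json(
    purrr::map(cells, function(res) {
      if (inherits(res, "error")) list(error = conditionMessage(res))
      else list(method = res$method, mean_accuracy = res$mean_accuracy,
                se = res$se, folds = res$folds)
    }),
    paths$cells, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config$hash,
         package_version = as.character(utils::packageVersion("traitrank")),
         r_version = R.version.string,
         config = config$raw),
    paths$metadata, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", sprintf("artifacts in %s", out_dir))
  invisible(list(status = 0L, accuracy_table = grid, paths = paths))
}

#' Path of the bundled canonical run configuration
#'
#' The canonical benchmark: p = 25 equicorrelated traits
#' (compound symmetry, rho = 0.3), n = 150 per class, mean shift solved
#' so the full-feature Bayes accuracy is 0.99, LDA and linear-SVM
#' classifiers swept over fractions 10%..50% and 100% under 10 repeats of
#' stratified 10-fold CV.
#'
#' @return File path of the YAML config.
#' @export
canonical_config_path <- function() {
  system.file("extdata", "canonical.yaml", package = "traitrank",
              mustWork = TRUE)
}
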