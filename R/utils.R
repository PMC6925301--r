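# Shared helpers: trait-column resolution, seed derivation, small checks.

# Columns that are never traits unless explicitly requested.
.reserved_cols <- c("sample_id", "label")

#' Identify trait columns of a trait table
#'
#' Trait columns are all numeric columns of `data` except `sample_id`,
#' `label`, and any columns named in `meta`. Most functions in the package
#' accept an explicit `traits` character vector; when it is `NULL` this
#' convention applies.
#'
#' @param data A trait table (data frame).
#' @param traits Optional character vector of trait column names; `NULL`
#'   means "resolve by convention".
#' @param meta Additional metadata column names to exclude.
#' @return Character vector of trait column names.
#' @export
trait_cols <- function(data, traits = NULL, meta = character()) {
  if (!is.null(traits)) {
    missing <- setdiff(traits, names(data))
    if (length(missing) > 0) {
      abort(paste0("Trait column(s) not found: ", toString(missing)),
            class = "traitrank_schema_error")
    }
    return(traits)
  }
  candidates <- setdiff(names(data), c(.reserved_cols, meta))
  candidates[vapply(data[candidates], is.numeric, logical(1))]
}

# Extract the numeric trait matrix (rows = samples) with column names.
trait_matrix <- function(data, traits) {
  m <- as.matrix(data[traits])
  if (!is.numeric(m)) {
    abort("Trait columns must all be numeric.", class = "traitrank_schema_error")
  }
  m
}

check_binary_labels <- function(y) {
  y <- as.factor(y)
  lv <- levels(droplevels(y))
  if (length(lv) < 2) {
    abort("Classification requires two classes; only one present in `label`.",
          class = "traitrank_label_error")
  }
  if (length(lv) > 2) {
    abort(paste0("Only binary labels are supported; got classes: ",
                 toString(lv)),
          class = "traitrank_label_error")
  }
  factor(y, levels = lv)
}

#' Derive a module-level seed from a global seed
#'
#' A single run seed is expanded into per-stage seeds by hashing a stage
#' label and folding it into the global seed. This keeps stages decoupled:
#' re-running one stage never consumes another stage's random stream.
#'
#' @param seed Integer global seed.
#' @param what Character stage label (e.g. `"simulate"`, `"folds"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, what) {
  offset <- strtoi(substr(rlang::hash(what), 1, 7), base = 16L)
  as.integer((as.double(seed) + offset) %% (.Machine$integer.max - 1))
}

# Run `expr` under a local RNG seeded with `seed`, leaving the caller's
# random stream untouched. seed = NULL runs unseeded.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# CPU seconds (user + system) consumed so far by this process. Used for
# per-cell runtime accounting: robust to scheduler and co-process noise,
# unlike wall-clock time.
cpu_seconds <- function() {
  pt <- proc.time()
  pt[["user.self"]] + pt[["sys.self"]]
}
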