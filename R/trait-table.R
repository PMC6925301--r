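# Trait-table CSV dialect: `sample_id`, metadata columns (`label`
# mandatory), then uniquely named numeric trait columns. Decimal point is
# '.', column order is deterministic on write so identical tables produce
# identical files.

#' Read a trait table from CSV
#'
#' Parses the package's CSV dialect: a header row, a `sample_id` column,
#' a label column, optional declared metadata columns, and all remaining
#' columns as numeric traits. Duplicate trait headers and non-numeric
#' trait cells are schema errors reported with coordinates.
#'
#' @param path CSV file path.
#' @param label Name of the label column (default `"label"`).
#' @param meta Character vector of metadata column names (kept as-is, not
#'   parsed as traits).
#' @return A tibble with `sample_id`, `label` (factor), metadata columns,
#'   then numeric trait columns.
#' @export
read_trait_csv <- function(path, label = "label", meta = character()) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "traitrank_io_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  dup <- unique(hdr[duplicated(hdr)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate column header(s): ", toString(dup)),
          class = "traitrank_schema_error")
  }
  for (required in c("sample_id", label)) {
    if (!required %in% hdr) {
      abort(paste0("Missing required column `", required, "` in ", path),
            class = "traitrank_schema_error")
    }
  }
  trait_names <- setdiff(hdr, c("sample_id", label, meta))
  spec <- c(
    setNames(list(readr::col_character()), "sample_id"),
    setNames(list(readr::col_character()), label),
    setNames(rep(list(readr::col_guess()), length(meta)), meta),
    setNames(rep(list(readr::col_double()), length(trait_names)), trait_names)
  )
  # readr warns on parse problems; we inspect problems() and raise a
  # schema error with coordinates instead
  data <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols, spec),
                    show_col_types = FALSE))
  problems <- readr::problems(data)
  if (nrow(problems) > 0) {
    p1 <- problems[1, ]
    abort(sprintf(
      "Non-numeric trait cell at row %d, column %d (expected %s, got \"%s\").",
      p1$row, p1$col, p1$expected, p1$actual),
      class = "traitrank_schema_error")
  }
  if (label != "label") {
    names(data)[names(data) == label] <- "label"
  }
  data$label <- factor(data$label)
  data <- data[c("sample_id", "label", meta, trait_names)]
  validate_trait_table(data, meta = meta)
  data
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_csv()]: writes `sample_id`, `label`, metadata,
#' then trait columns, in that deterministic order.
#'
#' @param data Trait table tibble.
#' @param path Output path.
#' @param meta Metadata column names to place before the traits.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(data, path, meta = character()) {
  validate_trait_table(data, meta = meta)
  traits <- trait_cols(data, meta = meta)
  readr::write_csv(data[c("sample_id", "label", meta, traits)], path,
                   progress = FALSE)
  invisible(path)
}

#' Validate the trait-table contract
#'
#' Checks the structural invariants every stage of the pipeline relies on:
#' required columns present, unique sample ids and trait names, numeric
#' trait columns, and labels from a finite set.
#'
#' @inheritParams write_trait_csv
#' @return `data`, invisibly.
#' @export
validate_trait_table <- function(data, meta = character()) {
  if (!is.data.frame(data)) {
    abort("A trait table must be a data frame.",
          class = "traitrank_schema_error")
  }
  for (required in c("sample_id", "label")) {
    if (!required %in% names(data)) {
      abort(paste0("Missing required column `", required, "`."),
            class = "traitrank_schema_error")
    }
  }
  dup <- unique(names(data)[duplicated(names(data))])
  if (length(dup) > 0) {
    abort(paste0("Duplicate column name(s): ", toString(dup)),
          class = "traitrank_schema_error")
  }
  traits <- trait_cols(data, meta = meta)
  non_numeric <- traits[!vapply(data[traits], is.numeric, logical(1))]
  if (length(non_numeric) > 0) {
    abort(paste0("Non-numeric trait column(s): ", toString(non_numeric)),
          class = "traitrank_schema_error")
  }
  invisible(data)
}
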