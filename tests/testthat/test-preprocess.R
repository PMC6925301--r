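make_table <- function(values, labels = NULL) {
  n <- nrow(values)
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    label = factor(labels %||% rep(c("0", "1"), length.out = n))) |>
    dplyr::bind_cols(tibble::as_tibble(values))
}

test_that("drop_empty_values implements the three policies", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(NULL, c("t1", "t2")))
  d <- make_table(X)
  # no zeros: identity, empty trace
  res <- drop_empty_values(d)
  expect_equal(res$data, d)
  expect_equal(nrow(res$trace$removed), 0)
  # single zero at (s2, t1): drop_sample leaves 2 rows
  d2 <- d; d2$t1[2] <- 0
  res2 <- drop_empty_values(d2, policy = "drop_sample")
  expect_equal(nrow(res2$data), 2)
  expect_equal(res2$trace$removed$id, "s02")
  # all-zero trait dropped under drop_trait at cutoff 0.5
  d3 <- d; d3$t1 <- 0
  res3 <- drop_empty_values(d3, policy = "drop_trait", cutoff = 0.5)
  expect_false("t1" %in% names(res3$data))
  expect_equal(nrow(res3$data), 3)
  # mask leaves NAs in place
  res4 <- drop_empty_values(d2, policy = "mask")
  expect_true(is.na(res4$data$t1[2]))
  # zero-exempt columns survive untouched
  res5 <- drop_empty_values(d2, policy = "drop_sample", zero_as_missing = "t2")
  expect_equal(res5$data, d2)
})

test_that("dropping every trait is an error, not an empty table", {
  d <- make_table(matrix(0, 4, 2, dimnames = list(NULL, c("t1", "t2"))))
  expect_error(drop_empty_values(d, policy = "drop_trait", cutoff = 0.5),
               class = "traitrank_empty_result_error")
})

test_that("outlier cells are masked per group without touching other traits", {
  set.seed(5)
  d <- make_table(matrix(rnorm(60), 30, 2,
                         dimnames = list(NULL, c("t1", "t2"))),
                  labels = rep(c("0", "1"), each = 15))
  d$genotype <- rep(c("g1", "g2"), 15)
  d$t1[7] <- 40  # gross outlier in one group
  res <- remove_outliers(d, method = "grubbs", group_by = "genotype",
                         policy = "mask")
  expect_true(is.na(res$data$t1[7]))
  expect_equal(res$data$t2, d$t2)  # untouched trait identical
  expect_equal(res$report$sample_id, "s07")
  # retained values are never modified
  ok <- !is.na(res$data$t1)
  expect_identical(res$data$t1[ok], d$t1[ok])
})

test_that("reproducibility filter keeps correlated traits, drops shuffled ones", {
  set.seed(9)
  n_units <- 100
  base <- rnorm(n_units)
  d <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(2 * n_units)),
    label = factor(rep(c("0", "1"), n_units)),
    unit = rep(sprintf("u%03d", seq_len(n_units)), each = 2),
    rep_id = rep(1:2, n_units),
    good = rep(base, each = 2) + rnorm(2 * n_units, 0, 0.1),
    perfect = rep(base, each = 2),
    shuffled = c(rbind(base, sample(base))))
  res <- reproducibility_filter(d, unit = "unit", replicate = "rep_id",
                                r_min = 0.5)
  expect_true(all(c("good", "perfect") %in% names(res$data)))
  expect_false("shuffled" %in% names(res$data))
  r_perfect <- res$correlations$r[res$correlations$trait == "perfect"]
  expect_equal(r_perfect, 1, tolerance = 1e-12)
  # vacuous threshold removes nothing
  res0 <- reproducibility_filter(d, unit = "unit", replicate = "rep_id",
                                 r_min = 0)
  expect_equal(nrow(res0$trace$removed), 0)
})

test_that("independently shuffled replicates are removed in >= 95% of runs", {
  removed <- vapply(1:40, function(i) {
    set.seed(200 + i)
    n_units <- 100
    base <- rnorm(n_units)
    d <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(2 * n_units)),
      label = factor(rep(c("0", "1"), n_units)),
      unit = rep(sprintf("u%03d", seq_len(n_units)), each = 2),
      rep_id = rep(1:2, n_units),
      anchor = rep(base, each = 2),
      shuffled = c(rbind(base, sample(base))))
    res <- reproducibility_filter(d, unit = "unit", replicate = "rep_id",
                                  r_min = 0.5)
    !"shuffled" %in% names(res$data)
  }, logical(1))
  expect_gte(mean(removed), 0.95)
})

test_that("traits with too few pairs are retained with a warning", {
  d <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:4),
    label = factor(c("0", "1", "0", "1")),
    unit = c("u1", "u1", "u2", "u2"),
    rep_id = c(1, 2, 1, 2),
    t1 = rnorm(4))
  expect_warning(
    res <- reproducibility_filter(d, unit = "unit", replicate = "rep_id"),
    class = "traitrank_not_assessable")
  expect_true("t1" %in% names(res$data))
})

test_that("VIF stepwise removal matches the car oracle and is idempotent", {
  set.seed(13)
  # orthogonal designs: all VIFs 1, nothing removed
  X <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4))) * 5
  colnames(X) <- paste0("t", 1:4)
  d <- make_table(X)
  res <- vif_stepwise(d, vif_max = 10)
  expect_equal(nrow(res$steps), 0)
  # duplicated column: infinite VIF, one copy removed first
  d2 <- d; d2$t5 <- d2$t1
  res2 <- vif_stepwise(d2, vif_max = 10)
  expect_equal(res2$steps$trait, "t1")  # tie at Inf -> earliest column
  expect_equal(res2$steps$vif, Inf)
  # near-collinear triple: exactly one removed, then stable
  X3 <- matrix(rnorm(60 * 2), 60, 2)
  X3 <- cbind(X3, X3[, 1] + X3[, 2] + rnorm(60, 0, 0.05))
  colnames(X3) <- paste0("t", 1:3)
  d3 <- make_table(X3)
  res3 <- vif_stepwise(d3, vif_max = 10)
  expect_equal(nrow(res3$steps), 1)
  rerun <- vif_stepwise(res3$data, vif_max = 10)
  expect_equal(nrow(rerun$steps), 0)
  expect_equal(rerun$data, res3$data)
  # the first-round VIFs agree with the car oracle
  got <- traitrank:::compute_vifs(X3)
  expect_equal(got, oracle_vifs(X3), tolerance = 1e-8)
})

test_that("VIF requires more samples than traits", {
  X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("t", 1:4)))
  expect_error(vif_stepwise(make_table(X)),
               class = "traitrank_dimensionality_error")
})

test_that("the pipeline applies stages in fixed order and traces them", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("ta", "tb", "tc")))
  d <- make_table(X, labels = rep(c("0", "1"), each = n / 2))
  d$zero_trait <- 0                     # all-empty image trait
  d$dup <- d$ta                         # redundant duplicate
  d$ta[5] <- 30                         # gross outlier cell
  res <- preprocess_traits(d, stages = c("missing", "outliers", "vif"),
                           policy = "drop_trait", cutoff = 0.5,
                           outlier_method = "grubbs", vif_max = 10)
  expect_false("zero_trait" %in% names(res$data))
  # one of the duplicated pair removed by VIF
  expect_equal(sum(c("ta", "dup") %in% names(res$data)), 1)
  expect_false("s05" %in% res$data$sample_id &&
                 "ta" %in% names(res$data) &&
                 isTRUE(res$data$ta[res$data$sample_id == "s05"] == 30))
  expect_named(res$traces, c("missing", "outliers", "vif"))
  td <- tidy(res)
  expect_equal(td$stage, c("drop_empty_values", "remove_outliers",
                           "vif_stepwise"))
  # trace counts are consistent
  expect_true(all(td$traits_after <= td$traits_before))
  # all stages disabled: identity
  same <- preprocess_traits(d, stages = character(0))
  expect_equal(same$data, d)
  expect_length(same$traces, 0)
})

test_that("filters are projections: a second pass changes nothing", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("t", 1:4)))
  d <- make_table(X, labels = rep(c("0", "1"), each = n / 2))
  d$t1[c(3, 17)] <- c(25, -30)
  d$t2[8] <- 0
  once <- preprocess_traits(d, stages = c("missing", "outliers", "vif"),
                            policy = "drop_sample",
                            outlier_method = "grubbs", vif_max = 10)
  twice <- preprocess_traits(once$data,
                             stages = c("missing", "outliers", "vif"),
                             policy = "drop_sample",
                             outlier_method = "grubbs", vif_max = 10)
  expect_equal(twice$data, once$data)
})

test_that("filter traces are serializable to JSON", {
  d <- make_table(matrix(rnorm(40), 20, 2,
                         dimnames = list(NULL, c("t1", "t2"))))
  d$t1[2] <- 0
  res <- preprocess_traits(d, stages = "missing")
  path <- withr::local_tempfile(fileext = ".json")
  write_trace_json(res, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$missing$samples_before, 20)
  expect_equal(parsed$missing$samples_after, 19)
})
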