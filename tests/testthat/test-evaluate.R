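test_that("fold partitions are exact and stratified", {
  y <- factor(rep(c("0", "1"), c(60, 40)))
  prot <- cv_protocol(k = 10, repeats = 3, seed = 5)
  folds <- cv_folds(y, prot)
  for (r in 1:3) {
    fr <- folds[folds$rep == r, ]
    # every sample tested exactly once per repeat
    expect_setequal(fr$row, seq_along(y))
    expect_equal(nrow(fr), length(y))
    # per-fold class counts within 1 of the global proportion
    for (f in 1:10) {
      rows <- fr$row[fr$fold == f]
      expect_equal(sum(y[rows] == "0"), 6)
      expect_equal(sum(y[rows] == "1"), 4)
    }
  }
  # protocol errors
  expect_error(cv_folds(factor(rep(c("0", "1"), c(5, 95))),
                        cv_protocol(k = 10)),
               class = "traitrank_protocol_error")
  expect_error(cv_protocol(k = 1), class = "traitrank_protocol_error")
})

test_that("a separable toy scores mean accuracy 1 with zero SE", {
  d <- make_separable_toy(20)
  cv <- repeated_cv(d, classifier_spec("lda"),
                    cv_protocol(k = 5, repeats = 3, seed = 2))
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$se, 0)
  g <- glance(cv)
  expect_equal(g$mean_accuracy, 1)
})

test_that("summary accuracy is the mean of per-repeat means", {
  d <- simulate_two_class(sim_config(20, 20, p = 4, epsilon = 1,
                                     cov_family = "identity", seed = 6))
  cv <- repeated_cv(d, classifier_spec("lda"),
                    cv_protocol(k = 4, repeats = 3, seed = 9))
  per_rep <- tapply(cv$folds$accuracy, cv$folds$rep, mean)
  expect_equal(cv$mean_accuracy, mean(per_rep))
  expect_equal(cv$se, sd(per_rep) / sqrt(3))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
})

test_that("chance-level data yields chance-level accuracy", {
  d <- simulate_two_class(sim_config(75, 75, p = 10, epsilon = 0,
                                     cov_family = "identity", seed = 12))
  cv <- repeated_cv(d, classifier_spec("lda"),
                    cv_protocol(k = 5, repeats = 4, seed = 3))
  expect_gt(cv$mean_accuracy, 0.40)
  expect_lt(cv$mean_accuracy, 0.60)
})

test_that("identical protocol seeds reproduce results exactly", {
  d <- simulate_two_class(sim_config(30, 30, p = 6, epsilon = 1,
                                     cov_family = "identity", seed = 14))
  run <- function() repeated_cv(d, classifier_spec("rf", n_trees = 50),
                                cv_protocol(k = 5, repeats = 2, seed = 8),
                                fraction = 0.5)
  r1 <- run(); r2 <- run()
  expect_identical(r1$folds$accuracy, r2$folds$accuracy)
  expect_identical(r1$mean_accuracy, r2$mean_accuracy)
})

test_that("fraction sweeps have the promised layout and bypass semantics", {
  d <- simulate_two_class(sim_config(30, 30, p = 10, epsilon = 1.2,
                                     cov_family = "identity", seed = 16))
  specs <- list(classifier_spec("lda"), classifier_spec("svm_linear"))
  prot <- cv_protocol(k = 5, repeats = 2, seed = 4)
  grid <- fraction_sweep(d, specs, fractions = c(0.2, 0.5, 1), protocol = prot)
  expect_equal(nrow(grid), 6)  # 2 methods x 3 fractions
  expect_equal(sort(unique(grid$at)), sort(c("20%", "50%", "100%")))
  expect_equal(grid$k_traits[grid$at == "100%"], c(10L, 10L))
  # the all-features column bypasses ranking
  expect_equal(grid$mean_rank_seconds[grid$at == "100%"], c(0, 0))
  expect_true(all(grid$mean_rank_seconds[grid$at != "100%"] > 0))
  # fractions {1} only: ranking never invoked anywhere
  g1 <- fraction_sweep(d, classifier_spec("lda"), fractions = 1,
                       protocol = prot)
  expect_equal(g1$mean_rank_seconds, 0)
  # tidy flags the best cell per method
  td <- tidy(grid)
  expect_equal(sum(td$is_best[td$method == "lda"]) >= 1, TRUE)
  expect_equal(nrow(td), 6)
})

test_that("count sweeps mirror fraction sweeps at equivalent cells", {
  d <- simulate_two_class(sim_config(30, 30, p = 10, epsilon = 1.2,
                                     cov_family = "identity", seed = 16))
  prot <- cv_protocol(k = 5, repeats = 2, seed = 4)
  gc_ <- count_sweep(d, classifier_spec("lda"), counts = c(2, 5, 10),
                     protocol = prot)
  expect_equal(nrow(gc_), 3)
  expect_equal(gc_$k_traits, c(2L, 5L, 10L))
  # counts {p} equals the all-features cell of fraction_sweep
  gf <- fraction_sweep(d, classifier_spec("lda"), fractions = 1,
                       protocol = prot)
  expect_equal(gc_$mean_accuracy[gc_$at == "10"], gf$mean_accuracy)
})

test_that("a failing cell is marked while other cells still complete", {
  d <- simulate_two_class(sim_config(30, 30, p = 4, epsilon = 1,
                                     cov_family = "identity", seed = 18))
  d$t05 <- 1  # constant trait: LDA refuses, SVM copes
  specs <- list(classifier_spec("lda"), classifier_spec("svm_linear"))
  grid <- suppressWarnings(
    fraction_sweep(d, specs, fractions = 1,
                   protocol = cv_protocol(k = 5, repeats = 1, seed = 1)))
  lda_row <- grid[grid$method == "lda", ]
  svm_row <- grid[grid$method == "svm_linear", ]
  expect_false(is.na(lda_row$error))
  expect_true(is.na(lda_row$mean_accuracy))
  expect_true(is.na(svm_row$error))
  expect_gt(svm_row$mean_accuracy, 0.6)
})

test_that("rank_once reuses one full-table ranking across folds", {
  d <- simulate_two_class(sim_config(40, 40, p = 8, epsilon = 1,
                                     cov_family = "identity", seed = 20))
  prot_once <- cv_protocol(k = 4, repeats = 2, rank_mode = "rank_once",
                           seed = 7)
  cv <- repeated_cv(d, classifier_spec("lda"), prot_once, fraction = 0.25)
  expect_equal(unique(cv$folds$k_traits), 2L)
  # subset identical across folds: the once-ranked top 2 of the full table
  rk_full <- svm_rfe(d)
  prot_in <- cv_protocol(k = 4, repeats = 2, rank_mode = "rank_inside_fold",
                         seed = 7)
  cv_fixed <- repeated_cv(d, classifier_spec("lda"), prot_in,
                          traits = select_top(rk_full, k = 2))
  expect_equal(cv$mean_accuracy, cv_fixed$mean_accuracy)
})

test_that("accuracy TSV layout is methods x fractions and stable", {
  d <- simulate_two_class(sim_config(20, 20, p = 4, epsilon = 1.5,
                                     cov_family = "identity", seed = 22))
  grid <- fraction_sweep(d, list(classifier_spec("lda")),
                         fractions = c(0.5, 1),
                         protocol = cv_protocol(k = 4, repeats = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_accuracy_tsv(grid, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(tab), c("method", "50%", "100%"))
  expect_equal(tab$method, "lda")
})
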