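test_that("covariance families match their definitions", {
  expect_equal(make_covariance("identity", p = 3, sigma = 1), diag(3))
  expect_equal(make_covariance("compound_symmetry", p = 2, sigma = 1, rho = 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2))
  V <- make_covariance("ar1", p = 3, sigma = 1, rho = 0.5)
  expect_equal(V, matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  # scaled versions
  expect_equal(diag(make_covariance("ar1", p = 4, sigma = 2, rho = -0.3)),
               rep(4, 4))
})

test_that("invalid covariance parameters raise configuration errors", {
  expect_error(make_covariance("compound_symmetry", p = 4, sigma = 1, rho = -0.5),
               class = "traitrank_config_error")
  expect_error(make_covariance("ar1", p = 3, sigma = 1, rho = 1),
               class = "traitrank_config_error")
  expect_error(make_covariance("identity", p = 3, sigma = 0),
               class = "traitrank_config_error")
  expect_error(make_covariance("custom", p = 2, V = matrix(c(1, 2, 2, 1), 2)),
               class = "traitrank_config_error")  # not positive definite
  expect_error(sim_config(0, 10, p = 2, epsilon = 1),
               class = "traitrank_config_error")
  expect_error(sim_config(10, 10, p = 2, epsilon = 1, informative_subset = 3),
               class = "traitrank_config_error")
})

test_that("simulated tables have the configured shape and labels", {
  cfg <- sim_config(n1 = 150, n2 = 150, p = 25, epsilon = 1,
                    cov_family = "identity", seed = 7)
  d <- simulate_two_class(cfg)
  expect_equal(nrow(d), 300)
  expect_length(trait_cols(d), 25)
  expect_equal(as.vector(table(d$label)), c(150, 150))
  expect_false(anyDuplicated(d$sample_id) > 0)
})

test_that("identical config and seed give bit-identical tables", {
  cfg <- sim_config(20, 20, p = 5, epsilon = 0.5, cov_family = "ar1",
                    rho = 0.4, seed = 11)
  expect_identical(simulate_two_class(cfg), simulate_two_class(cfg))
  # different replicate index gives a different draw
  expect_false(identical(simulate_two_class(cfg, replicate = 2),
                         simulate_two_class(cfg)))
})

test_that("class moments are recovered at large n", {
  cfg <- sim_config(5000, 5000, p = 4, epsilon = 1,
                    cov_family = "compound_symmetry", sigma = 2, rho = 0.3,
                    seed = 3)
  d <- simulate_two_class(cfg)
  X <- as.matrix(d[trait_cols(d)])
  for (cl in c("0", "1")) {
    Xc <- X[d$label == cl, ]
    mu_true <- if (cl == "0") rep(0, 4) else rep(1, 4)
    se_mean <- 2 / sqrt(5000)
    expect_true(all(abs(colMeans(Xc) - mu_true) < 4 * se_mean))
    V_hat <- cov(Xc)
    # SE of a covariance entry is ~ sqrt((v_ii v_jj + v_ij^2)/n)
    V <- cfg$V
    se_cov <- sqrt((outer(diag(V), diag(V)) + V^2) / 5000)
    expect_true(all(abs(V_hat - V) < 4 * se_cov))
  }
})

test_that("epsilon grids are consumed round-robin or at random", {
  cfg <- sim_config(5, 5, p = 2, epsilon = c(1, 2, 3),
                    cov_family = "identity", seed = 1)
  shift_of <- function(d) mean(as.matrix(d[d$label == "1", trait_cols(d)]))
  shifts <- vapply(1:4, function(r) shift_of(simulate_two_class(cfg, r)),
                   numeric(1))
  # noisy estimates of 1, 2, 3, then 1 again: check cyclic ordering
  expect_true(shifts[2] > shifts[1] && shifts[3] > shifts[2])
  expect_lt(shifts[4], shifts[3])
})

test_that("Bayes accuracy matches closed forms and is monotone in epsilon", {
  expect_equal(bayes_accuracy(sim_config(10, 10, p = 3, epsilon = 0,
                                         cov_family = "identity")), 0.5)
  expect_equal(bayes_accuracy(sim_config(10, 10, p = 1, epsilon = 2,
                                         cov_family = "identity")),
               pnorm(1), tolerance = 1e-12)
  expect_equal(bayes_accuracy(sim_config(10, 10, p = 2, epsilon = 1,
                                         cov_family = "identity")),
               pnorm(sqrt(2) / 2), tolerance = 1e-12)
  accs <- vapply(seq(0, 3, by = 0.25), function(e)
    bayes_accuracy(sim_config(10, 10, p = 6, epsilon = e, rho = 0.4)),
    numeric(1))
  expect_true(all(diff(accs) >= 0))
  # invariant under a joint permutation of the informative structure
  a1 <- bayes_accuracy(sim_config(10, 10, p = 5, epsilon = 1.3,
                                  cov_family = "ar1", rho = 0.5,
                                  informative_subset = c(1, 3)))
  a2 <- bayes_accuracy(sim_config(10, 10, p = 5, epsilon = 1.3,
                                  cov_family = "ar1", rho = 0.5,
                                  informative_subset = c(3, 5)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("epsilon_for_bayes inverts bayes_accuracy", {
  for (target in c(0.84, 0.95, 0.99)) {
    eps <- epsilon_for_bayes(target, p = 25, rho = 0.3)
    cfg <- sim_config(10, 10, p = 25, epsilon = eps, rho = 0.3)
    expect_equal(bayes_accuracy(cfg), target, tolerance = 1e-10)
  }
  eps <- epsilon_for_bayes(0.9, p = 10, cov_family = "identity",
                           informative_subset = 1:3)
  cfg <- sim_config(10, 10, p = 10, epsilon = eps, cov_family = "identity",
                    informative_subset = 1:3)
  expect_equal(bayes_accuracy(cfg), 0.9, tolerance = 1e-10)
})

test_that("traits outside the informative subset carry no class signal", {
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(40, 40, p = 4, epsilon = 2, cov_family = "identity",
                      informative_subset = 1:2, seed = 1000 + r)
    d <- simulate_two_class(cfg)
    # t03, t04 are null traits; two-sample t-test at alpha = 0.01
    for (tc in c("t03", "t04")) {
      p <- t.test(d[[tc]][d$label == "0"], d[[tc]][d$label == "1"])$p.value
      if (p < 0.01) hits <- hits + 1L
    }
  }
  # 200 null tests at alpha = 0.01: expect ~2 false positives, allow slack
  expect_lte(hits, 8L)
})
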