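# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different computational routes from the package:
# the SVM weights come from a generic interior-point QP solve of the dual
# (kernlab), VIFs from car::vif, LDA from first-principles pooled
# covariance, and the outlier statistics from hand-written formulas.

# Soft-margin linear SVM primal weights via the dual QP:
#   min_a 1/2 a' H a - 1' a,  H = (yy') * (XX'),  0 <= a <= C,  y'a = 0
oracle_svm_weights <- function(X, y, C = 1) {
  y <- factor(y)
  ypm <- ifelse(y == levels(y)[1], 1, -1)
  n <- nrow(X)
  G <- (ypm %*% t(ypm)) * (X %*% t(X))
  # the Gram matrix is rank-deficient whenever n > p, and at very high
  # target precision the interior-point KKT system can go singular as the
  # iterates approach the face; escalate the ridge and relax the precision
  # until the solve succeeds (order comparisons need ~4 figures, not 9)
  settings <- list(c(1e-9, 9), c(1e-9, 7), c(1e-7, 7), c(1e-5, 7),
                   c(1e-3, 6), c(1e-2, 6), c(1e-1, 6))
  sol <- NULL
  for (s in settings) {
    sol <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = G + diag(s[1], n),
                    A = matrix(ypm, 1), b = 0,
                    l = rep(0, n), u = rep(C, n), r = 0,
                    sigf = s[2], maxiter = 100),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  a <- kernlab::primal(sol)
  drop(t(X) %*% (a * ypm))
}

# RFE elimination order (column indices, worst first) by the QP oracle.
oracle_rfe_order <- function(X, y, C = 1) {
  surv <- seq_len(ncol(X))
  elim <- integer(0)
  while (length(surv) > 1) {
    w <- oracle_svm_weights(X[, surv, drop = FALSE], y, C)
    crit <- w^2
    g <- which(crit == min(crit))[1]
    elim <- c(elim, surv[g])
    surv <- surv[-g]
  }
  c(elim, surv)
}

# Iterated two-sided Grubbs by direct formula; returns flagged indices
# (original positions) and the statistic/critical value per round.
oracle_grubbs <- function(x, alpha = 0.05, max_iter = 20) {
  idx <- seq_along(x)
  flagged <- integer(0)
  stats <- crits <- numeric(0)
  for (i in seq_len(max_iter)) {
    n <- length(idx)
    if (n < 3) break
    v <- x[idx]
    m <- sum(v) / n
    s <- sqrt(sum((v - m)^2) / (n - 1))
    if (s == 0) break
    d <- abs(v - m)
    G <- max(d) / s
    tq <- qt(1 - alpha / (2 * n), df = n - 2)
    Gc <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= Gc) break
    worst <- which(d == max(d))[1]
    flagged <- c(flagged, idx[worst])
    stats <- c(stats, G)
    crits <- c(crits, Gc)
    idx <- idx[-worst]
  }
  list(flagged = flagged, statistic = stats, critical = crits)
}

# Bonferroni-adjusted outlier p-values by the hand-written externally
# studentized residual formula (location-only model).
oracle_bonferroni_p <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s <- sqrt(sum(e^2) / (n - 1))
  r <- e / (s * sqrt(1 - 1 / n))              # internally studentized
  t_ext <- r * sqrt((n - 2) / (n - 1 - r^2))  # externally studentized
  pmin(1, 2 * pt(-abs(t_ext), df = n - 2) * n)
}

# VIFs through car::vif on a regression with an irrelevant response.
oracle_vifs <- function(X) {
  df <- as.data.frame(X)
  df$.y <- seq_len(nrow(X)) + rep(c(0.1, -0.1), length.out = nrow(X))
  unname(car::vif(lm(.y ~ ., data = df)))
}

# From-first-principles LDA with equal priors: pooled within-class
# covariance, classify to the nearer class in Mahalanobis metric.
oracle_lda_predict <- function(Xtr, ytr, Xte) {
  ytr <- factor(ytr)
  lv <- levels(ytr)
  mus <- lapply(lv, function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  Sp <- Reduce(`+`, lapply(lv, function(cl) {
    Xc <- scale(Xtr[ytr == cl, , drop = FALSE], center = TRUE, scale = FALSE)
    crossprod(Xc)
  })) / (nrow(Xtr) - length(lv))
  Sinv <- solve(Sp)
  scores <- sapply(mus, function(mu) {
    Xte %*% Sinv %*% mu - 0.5 * drop(t(mu) %*% Sinv %*% mu)
  })
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

# A linearly separable 2-trait toy: trait 1 carries all the signal; the
# zigzag in trait 2 keeps it within-class non-collinear with trait 1.
make_separable_toy <- function(n_per_class = 10) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(2 * n_per_class)),
    label = factor(rep(c("0", "1"), each = n_per_class)),
    t01 = c(seq(-2, -1, length.out = n_per_class),
            seq(1, 2, length.out = n_per_class)),
    t02 = rep(seq(-0.5, 0.5, length.out = n_per_class), 2) +
      rep(c(0.11, -0.07), length.out = 2 * n_per_class))
}

# Random small binary-labelled matrix for oracle comparisons.
random_instance <- function(p, n) {
  n1 <- ceiling(n / 2)
  y <- c(rep("0", n1), rep("1", n - n1))
  X <- matrix(rnorm(n * p), n, p)
  X[y == "1", ] <- X[y == "1", ] + rnorm(p)
  colnames(X) <- sprintf("t%02d", seq_len(p))
  list(X = X, y = factor(y))
}
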