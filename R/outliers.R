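# Single-outlier tests for replicated trait measurements. Both assume
# approximate normality of repeated measures within a replicate group.

#' Grubbs test for outliers in a numeric vector
#'
#' Two-sided Grubbs test: the statistic is `G = max |x_i - mean| / sd`,
#' compared against the critical value
#' `G_crit = (N-1)/sqrt(N) * sqrt(t^2 / (N - 2 + t^2))` where `t` is the
#' upper `alpha / (2N)` quantile of the t distribution on `N - 2` degrees
#' of freedom. With `iterate = TRUE` the flagged point is removed and the
#' test repeated until nothing is flagged or fewer than 3 points remain.
#'
#' When two extremes are exactly equidistant from the mean the one with
#' the lower index is flagged, for determinism.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param iterate Repeat after removing each flagged point (default TRUE).
#' @param max_iter Cap on removal rounds.
#' @return An `outlier_report`: a tibble with columns `index`, `value`,
#'   `statistic`, `threshold`, `iteration`, carrying attributes `method`
#'   and `alpha`. Zero rows when nothing is flagged.
#' @examples
#' grubbs_outliers(c(1, 2, 3, 100))
#' @export
grubbs_outliers <- function(values, alpha = 0.05, iterate = TRUE,
                            max_iter = 20L) {
  if (length(values) < 3 || sum(is.finite(values)) < 3) {
    abort("Grubbs test needs at least 3 finite values.",
          class = "traitrank_insufficient_data_error")
  }
  idx <- which(is.finite(values))
  flagged <- empty_outlier_report("grubbs", alpha)
  for (iteration in seq_len(if (iterate) max_iter else 1L)) {
    x <- values[idx]
    n <- length(x)
    if (n < 3) break
    s <- sd(x)
    if (s < .Machine$double.eps * max(1, max(abs(x)))) {
      warn("Zero variance: Grubbs test degenerate, nothing flagged.",
           class = "traitrank_degenerate_input")
      break
    }
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    gc <- grubbs_critical(n, alpha)
    if (g <= gc) break
    worst <- which(dev == max(dev))[1]  # equidistant tie: lowest index
    flagged <- dplyr::bind_rows(flagged, tibble::tibble(
      index = idx[worst], value = x[worst],
      statistic = g, threshold = gc, iteration = iteration))
    idx <- idx[-worst]
  }
  attr(flagged, "method") <- "grubbs"
  attr(flagged, "alpha") <- alpha
  flagged
}

# Two-sided Grubbs critical value from the t quantile.
grubbs_critical <- function(n, alpha) {
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Bonferroni outlier test
#'
#' Computes the externally studentized residual of each observation from
#' the location-only (intercept) model, its two-sided p-value on `N - 2`
#' degrees of freedom, and the Bonferroni-adjusted p-value
#' `min(1, N * p)`. Observations with adjusted p below `alpha` are
#' flagged.
#'
#' @param values Numeric vector, length >= 4.
#' @param alpha Family-wise significance level.
#' @return An `outlier_report` tibble with columns `index`, `value`,
#'   `statistic` (studentized residual), `p_adjusted`, `iteration`.
#' @examples
#' bonferroni_outliers(c(1, 2, 3, 100))
#' @export
bonferroni_outliers <- function(values, alpha = 0.05) {
  idx <- which(is.finite(values))
  n <- length(idx)
  if (n < 4) {
    abort("Bonferroni outlier test needs at least 4 finite values.",
          class = "traitrank_insufficient_data_error")
  }
  x <- values[idx]
  if (sd(x) < .Machine$double.eps * max(1, max(abs(x)))) {
    warn("Zero variance: Bonferroni test degenerate, nothing flagged.",
         class = "traitrank_degenerate_input")
    out <- empty_outlier_report("bonferroni", alpha)
    out$p_adjusted <- numeric(0)
    return(out)
  }
  t_ext <- rstudent(lm(x ~ 1))
  p_adj <- pmin(1, 2 * pt(-abs(t_ext), df = n - 2) * n)
  hit <- which(p_adj < alpha)
  flagged <- tibble::tibble(
    index = idx[hit], value = x[hit],
    statistic = t_ext[hit], p_adjusted = p_adj[hit],
    iteration = rep(1L, length(hit)))
  attr(flagged, "method") <- "bonferroni"
  attr(flagged, "alpha") <- alpha
  flagged
}

empty_outlier_report <- function(method, alpha) {
  out <- tibble::tibble(index = integer(0), value = numeric(0),
                        statistic = numeric(0), threshold = numeric(0),
                        iteration = integer(0))
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}
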