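# Shared statistics: Spearman (with the trend-test conventions), partial
# Spearman on ranks, Goodman-Kruskal gamma with a permutation p-value,
# Mann-Whitney U and exact binomial wrappers, loess smoothing.

#' Spearman correlation with average ranks and t-approximation p-value
#'
#' Average ranks for ties; two-tailed p from the t approximation with
#' n - 2 degrees of freedom. Constant input (zero variance in either
#' vector) yields `rho = 0`, `p = 1` rather than `NA`.
#'
#' @param x,y Equal-length numeric vectors.
#' @return One-row tibble `rho`, `p`, `n`.
#' @export
spearman_trend <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  check_that(n >= 3, "need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(rho = 0, p = 1, n = n))
  }
  rho <- cor(rx, ry)
  p <- spearman_p_tapprox(rho, n)
  tibble(rho = rho, p = p, n = n)
}

# two-tailed t-approximation p for a Spearman rho
spearman_p_tapprox <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all vectors (average ranks), residualises `x` and `y`
#' on the controls by least squares, and correlates the residuals.
#' Two-tailed p from the t approximation with `n - 2 - k` degrees of
#' freedom (`k` controls).
#'
#' @param x,y Numeric vectors.
#' @param controls A numeric vector, or a list/data frame of covariate
#'   vectors to control for.
#' @return One-row tibble `rho_partial`, `p`, `n`, `n_controls`.
#' @export
partial_spearman <- function(x, y, controls) {
  if (is.numeric(controls)) controls <- list(controls)
  z <- as.data.frame(controls)
  n <- length(x)
  k <- ncol(z)
  check_that(length(y) == n && all(vapply(z, length, 1L) == n),
             "all vectors must have equal length")
  check_that(n > k + 2, "too few observations for the number of controls")
  check_that(sd(x) > 0 && sd(y) > 0, "constant vector supplied")
  rx <- rank(x); ry <- rank(y)
  rz <- as.matrix(as.data.frame(lapply(z, rank)))
  res_x <- residuals(lm(rx ~ rz))
  res_y <- residuals(lm(ry ~ rz))
  if (sd(res_x) == 0 || sd(res_y) == 0) {
    return(tibble(rho_partial = 0, p = 1, n = n, n_controls = k))
  }
  rho <- cor(res_x, res_y)
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * pt(-abs(tstat), df = df)
  }
  tibble(rho_partial = rho, p = p, n = n, n_controls = k)
}

#' Goodman-Kruskal gamma with a permutation p-value
#'
#' Gamma = (C - D) / (C + D) over pairs untied in both variables. The
#' p-value is one-sided (greater): `x` is shuffled against `y` `m` times
#' and `p = (n + 1) / (m + 1)` where `n` counts permuted gammas greater
#' than or equal to the observed one (ties with the observed value are
#' counted, conservatively).
#'
#' @param x,y Equal-length ordinal/numeric vectors (length >= 3).
#' @param m Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Object of class `gk_gamma`: list with `gamma`, `p_perm`,
#'   `concordant`, `discordant`, `m`, `n_ge`.
#' @export
goodman_kruskal_gamma_perm <- function(x, y, m = 1000, seed = 1L) {
  n <- length(x)
  check_that(n >= 3 && length(y) == n,
             "x and y must have equal length >= 3")
  obs <- gk_gamma_stat(x, y)
  check_that(is.finite(obs), "all pairs tied: gamma undefined")
  set.seed(seed)
  perm <- vapply(seq_len(m), function(i) gk_gamma_stat(sample(x), y),
                 numeric(1))
  n_ge <- sum(perm >= obs, na.rm = TRUE)
  structure(
    list(gamma = as.numeric(obs), p_perm = (n_ge + 1) / (m + 1),
         concordant = attr(obs, "C"), discordant = attr(obs, "D"),
         m = m, n_ge = n_ge),
    class = "gk_gamma"
  )
}

# gamma statistic; NA when C + D == 0
gk_gamma_stat <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  prod <- sx[up] * sy[up]
  C <- sum(prod > 0); D <- sum(prod < 0)
  if (C + D == 0) return(NA_real_)
  structure((C - D) / (C + D), C = C, D = D)
}

#' @export
print.gk_gamma <- function(x, ...) {
  cat("Goodman-Kruskal gamma = ", format(x$gamma, digits = 4),
      " (C = ", x$concordant, ", D = ", x$discordant, ")\n",
      "permutation p = ", format(x$p_perm, digits = 4),
      " [(n+1)/(m+1), n = ", x$n_ge, ", m = ", x$m, "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gk_gamma <- function(x, ...) {
  tibble(estimate = x$gamma, p.value = x$p_perm,
         concordant = x$concordant, discordant = x$discordant,
         n_permutations = x$m, method = "Goodman-Kruskal gamma (permutation)")
}

#' Mann-Whitney U test wrapper
#'
#' Exact enumeration for small samples (both groups <= 20, no ties),
#' normal approximation with tie correction otherwise; mirrors
#' [stats::wilcox.test()] defaults.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return One-row tibble `p`, `u`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  check_that(length(a) > 0 && length(b) > 0, "a group is empty")
  if (length(a) == 1 && length(b) == 1) {
    warn("single observation per group: test is degenerate")
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative))
  tibble(p = wt$p.value, u = unname(wt$statistic),
         median_a = median(a), median_b = median(b),
         n_a = length(a), n_b = length(b))
}

#' Exact two-sided binomial sign test
#'
#' Standard two-sided exact test (sum of tail probabilities no larger
#' than the observed one, capped at 1) at p = 0.5.
#'
#' @param n_success,n_trials Counts.
#' @return One-row tibble `p`, `n_success`, `n_trials`.
#' @export
exact_binomial_sign_test <- function(n_success, n_trials) {
  check_that(n_trials > 0, "no informative pairs")
  bt <- binom.test(n_success, n_trials, p = 0.5)
  tibble(p = bt$p.value, n_success = n_success, n_trials = n_trials)
}

#' Loess fit with residuals
#'
#' Locally weighted linear regression (tricube weights) via
#' [stats::loess()].
#'
#' @param x,y Numeric vectors (>= 10 points).
#' @param span Smoothing span in (0, 1].
#' @param degree Local polynomial degree (default 1).
#' @return Tibble `x`, `y`, `fitted`, `residual` in input order.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1) {
  check_that(length(x) == length(y), "x and y must have equal length")
  check_that(length(x) >= 10, "need at least 10 points for loess")
  check_that(span > 0 && span <= 1, "span must be in (0, 1]")
  check_that(sd(x) > 0, "all x values are equal")
  fit <- loess(y ~ x, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  fitted <- predict(fit, newdata = data.frame(x = x))
  tibble(x = x, y = y, fitted = fitted, residual = y - fitted)
}
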