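# Statistical layer: circular statistics, rank-based tests and the
# exponential developmental-trend model.

wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180  # angles live in (-180, 180]
  w
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is uniformly distributed on the circle
#' using the mean resultant length `R_bar = |sum(exp(i * theta))| / n` and
#' `Z = n * R_bar^2`. The p-value uses the standard higher-order series
#' approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clipped to (0, 1]. The p-value is invariant under global rotation of the
#' sample.
#'
#' @param angles Angles in degrees (n >= 3); `NA` values are dropped.
#' @return An object of class `rayleigh_test`: `mean_angle` (degrees),
#'   `R_bar`, `Z`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 3) stop("Rayleigh test needs at least 3 angles")
  th <- angles * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  R_bar <- sqrt(C^2 + S^2) / n
  Z <- n * R_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(mean_angle = wrap_angle(atan2(S, C) * 180 / pi),
                 R_bar = R_bar, Z = Z, p = p, n = n),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test of uniformity: n = %d, R_bar = %.3f, Z = %.3f, p = %.3g\n",
              x$n, x$R_bar, x$Z, x$p))
  cat(sprintf("  mean angle %.1f deg\n", x$mean_angle))
  invisible(x)
}

#' Circular mean and standard error
#'
#' The circular mean is the argument of the resultant vector. The standard
#' error follows from the circular dispersion
#' `delta = (1 - rho2) / (2 * rho1^2)` (with `rho1` the mean resultant
#' length and `rho2` the mean resultant of the doubled centred angles):
#' `sem = sqrt(delta / n)`, converted to degrees.
#'
#' @param angles Angles in degrees (n >= 2); `NA` dropped.
#' @return List with `mean` and `sem`, both in degrees, plus `n`.
#' @export
circular_mean_sem <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  th <- angles * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  rho1 <- sqrt(C^2 + S^2)
  if (rho1 < 1e-12) stop("mean resultant length is zero: circular mean undefined")
  mu <- atan2(S, C)
  rho2 <- mean(cos(2 * (th - mu)))
  delta <- (1 - rho2) / (2 * rho1^2)
  list(mean = wrap_angle(mu * 180 / pi),
       sem = sqrt(max(delta, 0) / n) * 180 / pi,
       n = n)
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation with mid-rank handling of ties; two-sided p-value
#' (exact for small untied samples, t/Edgeworth approximation otherwise, as
#' provided by [stats::cor.test()]).
#'
#' @param x,y Equal-length numeric vectors (n >= 4).
#' @return An object of class `sep_test`: `statistic` (rho), `p`,
#'   `test_name`, `n_per_group`, `one_sided = FALSE`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(statistic = unname(ct$estimate), p = ct$p.value,
                 test_name = "Spearman rank correlation",
                 n_per_group = length(x), one_sided = FALSE),
            class = "sep_test")
}

#' One-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) comparison of two groups. The p-value is exact
#' (full enumeration of rank assignments) when the combined sample size is
#' at most 20 and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"less"` (group A shifted left of group B),
#'   `"greater"`, or `"two.sided"`.
#' @return An object of class `sep_test`: `statistic` (rank sum of group
#'   A), `p`, `test_name`, `n_per_group`, `one_sided`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n_a <- length(group_a); n_b <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (n_a + n_b) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic) + n_a * (n_a + 1) / 2,
                 p = wt$p.value,
                 test_name = sprintf("Wilcoxon rank sum (%s)",
                                     if (exact) "exact" else "normal approximation"),
                 n_per_group = c(n_a, n_b),
                 one_sided = alternative != "two.sided"),
            class = "sep_test")
}

#' @export
print.sep_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n",
              x$test_name, x$statistic, x$p,
              paste(x$n_per_group, collapse = " + "),
              if (x$one_sided) ", one-sided" else ""))
  invisible(x)
}

#' Fit an exponential developmental trend
#'
#' Least-squares fit of `value = a * exp(-b * (age - min(age))) + c` with
#' `b >= 0`, describing latencies (or other response characteristics) that
#' decay towards a mature asymptote over postnatal development. The rate
#' `b` is profiled: for each candidate `b` the conditionally linear
#' parameters `(a, c)` are solved by linear least squares, and the profiled
#' residual sum of squares is minimized over a multi-start grid refined by
#' golden-section search.
#'
#' @param ages Postnatal days (>= 4 distinct values).
#' @param values Observed values (e.g. latency in ms).
#' @param b_max Upper bound for the decay rate per day (default 3).
#' @return An object of class `exp_trend` with fields `a`, `b`, `c`,
#'   `residual_rms`, `n_points`, `age0` plus data and fitted values.
#'   Supports `coef`, `predict`, `fitted`, `residuals`, `print`, `plot`.
#' @examples
#' ages <- 8:16
#' fit <- fit_exponential_trend(ages, 30 * exp(-0.3 * (ages - 8)) + 15)
#' coef(fit)
#' @export
fit_exponential_trend <- function(ages, values, b_max = 3) {
  stopifnot(length(ages) == length(values))
  if (length(unique(ages)) < 4) stop("need at least 4 distinct ages")
  age0 <- min(ages)
  rss_coef <- function(b) {
    e <- exp(-b * (ages - age0))
    X <- cbind(1, e)
    qr_x <- qr(X)
    if (qr_x$rank < 2) {
      cc <- mean(values)
      return(list(rss = sum((values - cc)^2), a = 0, c = cc))
    }
    beta <- qr.coef(qr_x, values)
    res <- values - X %*% beta
    list(rss = sum(res^2), a = unname(beta[2]), c = unname(beta[1]))
  }
  grid <- seq(0, b_max, length.out = 61)
  rss_grid <- vapply(grid, function(b) rss_coef(b)$rss, numeric(1))
  if (all(!is.finite(rss_grid))) stop("exponential trend fit failed from all starts")
  i <- which.min(rss_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  b_hat <- if (lo < hi) stats::optimize(function(b) rss_coef(b)$rss,
                                        c(lo, hi), tol = 1e-10)$minimum else grid[i]
  if (rss_coef(b_hat)$rss > rss_grid[i]) b_hat <- grid[i]
  sol <- rss_coef(b_hat)
  fitted <- sol$a * exp(-b_hat * (ages - age0)) + sol$c
  structure(
    list(a = sol$a, b = b_hat, c = sol$c,
         residual_rms = sqrt(sol$rss / length(ages)),
         n_points = length(ages), age0 = age0,
         ages = ages, values = values, fitted = fitted),
    class = "exp_trend"
  )
}

#' @export
print.exp_trend <- function(x, ...) {
  cat("exponential developmental trend:\n")
  cat(sprintf("  value = %.4g * exp(-%.4g * (age - %g)) + %.4g\n",
              x$a, x$b, x$age0, x$c))
  cat(sprintf("  n = %d, residual RMS = %.4g\n", x$n_points, x$residual_rms))
  invisible(x)
}

#' @export
coef.exp_trend <- function(object, ...) c(a = object$a, b = object$b, c = object$c)

#' @export
fitted.exp_trend <- function(object, ...) object$fitted

#' @export
residuals.exp_trend <- function(object, ...) object$values - object$fitted

#' @rdname fit_exponential_trend
#' @param object,newdata `predict` method: `newdata` is a vector of ages
#'   (defaults to the fitted ages).
#' @param ... Unused.
#' @export
predict.exp_trend <- function(object, newdata = object$ages, ...) {
  object$a * exp(-object$b * (newdata - object$age0)) + object$c
}

#' @export
plot.exp_trend <- function(x, ...) {
  graphics::plot(x$ages, x$values, xlab = "postnatal day", ylab = "value",
                 pch = 19, ...)
  ord <- order(x$ages)
  aa <- seq(min(x$ages), max(x$ages), length.out = 200)
  graphics::lines(aa, predict(x, aa), lty = 2)
  invisible(x)
}

#' Group summary as mean and standard error of the mean
#'
#' @param x Numeric vector.
#' @return List with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}
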