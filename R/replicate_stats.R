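# Replicate statistics: mean, sample SD, t-based 95% confidence interval
# over repeated runs, and the paired two-tailed t-test (df = n - 1, critical
# |t| = 4.303 for three replicates at alpha = 0.05).

#' Summarize a replicate set
#'
#' @param values numeric vector of per-run scores (`n >= 2`, finite).
#' @param conf confidence level (default 0.95).
#' @return `list(mean, sd, ci_low, ci_high, n)`; the CI is
#'   `mean +/- t(1-(1-conf)/2, n-1) * sd / sqrt(n)`.
#' @export
summarize_replicates <- function(values, conf = 0.95) {
  if (length(values) < 2L) stop("need at least two replicates", call. = FALSE)
  if (!all(is.finite(values))) stop("replicate values must be finite", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  half <- t_critical(1 - conf, n - 1L) * s / sqrt(n)
  list(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

#' Two-tailed Student-t critical value
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (`>= 1`).
#' @return `qt(1 - alpha/2, df)`; 4.303 for `alpha = 0.05, df = 2`.
#' @export
t_critical <- function(alpha, df) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' Paired two-tailed t-test on replicate sets
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the per-run differences
#' `d = x - y`; significant when `|t|` exceeds the critical value at the
#' given alpha with `n - 1` degrees of freedom. Zero-variance differences are
#' handled explicitly: `t = 0` (not significant) when the mean difference is
#' also zero, else `t = +/-Inf` (significant).
#'
#' @param x,y equal-length numeric vectors paired by run index.
#' @param alpha significance level.
#' @return `list(t, significant, df, critical)`.
#' @export
paired_t <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("replicate sets must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two paired replicates", call. = FALSE)
  d <- x - y
  n <- length(d)
  crit <- t_critical(alpha, n - 1L)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (sd_d / sqrt(n))
  }
  list(t = t, significant = abs(t) > crit, df = n - 1L, critical = crit)
}

#' Format replicate columns in the mean(sd)[ci] table style
#'
#' @param values numeric vector of replicate scores.
#' @param digits decimal places.
#' @return A single string `"mean (sd) [lo, hi]"`.
#' @export
format_replicates <- function(values, digits = 4) {
  s <- summarize_replicates(values)
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  sprintf("%s (%s) [%s, %s]", fmt(s$mean), fmt(s$sd), fmt(s$ci_low), fmt(s$ci_high))
}
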