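# Population-level statistics: contingency chi-squared tests, proportions,
# t tests, and scaled JZS Bayes factors for null-favoring contrasts.

#' Pearson chi-squared test for a 2 x 2 table
#'
#' Uncorrected (no Yates continuity correction): X2 = N(ad - bc)^2 /
#' [(a+b)(c+d)(a+c)(b+d)], df = 1. Rows are groups, columns outcome
#' yes/no.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return List: `statistic`, `p`, `df`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  chi2_rxc(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
}

#' Pearson chi-squared test for an r x c table
#'
#' Sum of (O - E)^2 / E with expected counts from the margins;
#' df = (r-1)(c-1). No continuity correction.
#'
#' @param table numeric matrix of counts.
#' @return List: `statistic`, `p`, `df`, `expected`.
#' @export
chi2_rxc <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin: a row or column is all zero")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ht$expected == 0)) stop("zero expected cell count")
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Percentage of a count
#'
#' @param k,n counts with 0 <= k <= n, n > 0.
#' @return 100 * k / n, rounded to 2 decimal places.
#' @export
proportion_pct <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n, 2)
}

#' Scaled JZS Bayes factor for a t statistic
#'
#' Default-prior Bayes factor favoring the null (BF01) under the
#' Zellner-Siow setup: a Cauchy prior with scale `r` on the standardized
#' effect size. Computed by numerical integration of the Jeffreys-Zellner-
#' Siow g-integral; BF01 > 1 favors the null.
#'
#' @param t observed t statistic.
#' @param n1 first (or only) group size.
#' @param n2 second group size for a two-sample design; `NULL` (default)
#'   for one-sample.
#' @param r Cauchy prior scale on the effect size; default `sqrt(2)/2`.
#' @return List: `bf01`, `t`, `df`, `n_eff`, `r`, `design`.
#' @export
jzs_bayes_factor <- function(t, n1, n2 = NULL, r = sqrt(2) / 2) {
  stopifnot(r > 0, n1 >= 2)
  if (is.null(n2)) {
    n_eff <- n1; df <- n1 - 1; design <- "one_sample"
  } else {
    stopifnot(n2 >= 2)
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2; design <- "two_sample"
  }
  if (df < 1) stop("df must be >= 1")
  h1 <- stats::integrate(function(g) {
    a <- 1 + n_eff * g * r^2
    a^(-0.5) * (1 + t^2 / (a * df))^(-(df + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }, 0, Inf, rel.tol = 1e-8, stop.on.error = FALSE)
  if (h1$message != "OK" || !is.finite(h1$value) || h1$value <= 0)
    stop("JZS quadrature failed: ", h1$message,
         " (value = ", h1$value, ", abs.error = ", h1$abs.error, ")")
  h0 <- (1 + t^2 / df)^(-(df + 1) / 2)
  list(bf01 = h0 / h1$value, t = t, df = df, n_eff = n_eff, r = r,
       design = design)
}

#' Pooled-variance two-sample t test
#'
#' @param x,y numeric samples (>= 2 values each).
#' @return List: `t`, `df` (n1 + n2 - 2), `p` (two-sided).
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-sample t test against zero
#'
#' @param x numeric sample (>= 2 values).
#' @return List: `t`, `df` (n - 1), `p` (two-sided).
#' @export
one_sample_t <- function(x) {
  stopifnot(length(x) >= 2)
  if (stats::var(x) == 0) stop("zero variance")
  ht <- stats::t.test(x)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
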