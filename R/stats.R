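# Regularised incomplete beta I_x(a, b), evaluated by the standard
# continued-fraction expansion (modified Lentz), used for two-tailed t
# p-values without calling the distribution functions.
ibeta <- function(x, a, b) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= 0) return(0)
    if (xi >= 1) return(1)
    lbt <- lgamma(a + b) - lgamma(a) - lgamma(b) +
      a * log(xi) + b * log1p(-xi)
    if (xi < (a + 1) / (a + b + 2)) {
      exp(lbt) * beta_cf(xi, a, b) / a
    } else {
      1 - exp(lbt) * beta_cf(1 - xi, b, a) / b
    }
  }, numeric(1))
}

beta_cf <- function(x, a, b, max_iter = 200, eps = 3e-16) {
  tiny <- 1e-300
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < tiny) d <- tiny
  d <- 1 / d
  h <- d
  for (m in seq_len(max_iter)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    h <- h * d * c
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < eps) break
  }
  h
}

# Two-tailed p for a t statistic with (possibly fractional) df.
t_pvalue_two_tailed <- function(t, df) {
  ibeta(df / (df + t^2), df / 2, 0.5)
}

#' Two-sample t tests implemented from their formulas
#'
#' `welch_t()` is Welch's unequal-variance two-sample t test with
#' Welch–Satterthwaite degrees of freedom; `student_t()` is the classical
#' pooled-variance unpaired test with `n_a + n_b - 2` degrees of freedom.
#' Both report the two-tailed p-value, evaluated through a
#' continued-fraction incomplete-beta expansion of the t distribution.
#' The two coincide exactly when group variances and sizes are equal.
#'
#' @param a,b Numeric samples, each of size >= 2; the relevant variance
#'   (either group for Welch, pooled for Student) must be nonzero.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `test_kind`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(a, b) {
  check_samples(a, b)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) abort_invalid("Both samples are constant; t undefined.")
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  t_result(t, df, a, b, "welch")
}

#' @rdname welch_t
#' @export
student_t <- function(a, b) {
  check_samples(a, b)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) abort_invalid("Pooled variance is zero; t undefined.")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  t_result(t, df, a, b, "student")
}

check_samples <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    abort_invalid("Both samples must have >= 2 non-missing values.")
  }
}

t_result <- function(t, df, a, b, kind) {
  tibble::tibble(
    t_statistic = t, df = df,
    p_value = t_pvalue_two_tailed(t, df),
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    test_kind = kind)
}

#' Compare a smoking metric between germline-mutant and wild-type patients
#'
#' Groups patients by whether they carry at least one passing germline
#' DNA-repair variant and compares a smoking-related metric between the two
#' groups with a two-tailed two-sample t test. Patients with an undefined
#' metric (e.g. variants-per-pack-year in never-smokers) are excluded and
#' counted.
#'
#' @param patients Tibble with a logical `germline_mutant` column and the
#'   metric column.
#' @param metric Name of the metric column, one of `smoking_fraction`,
#'   `burden_per_mb`, `smoking_variants_per_py` (any numeric column works).
#' @param test_kind `"welch"` (default) or `"student"`.
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @export
compare_by_germline_status <- function(patients,
                                       metric = "smoking_fraction",
                                       test_kind = c("welch", "student")) {
  test_kind <- match.arg(test_kind)
  if (!metric %in% names(patients)) {
    abort_invalid(sprintf("Metric column '%s' not found.", metric))
  }
  if (!is.logical(patients$germline_mutant)) {
    abort_invalid("`germline_mutant` must be logical.")
  }
  x <- patients[[metric]]
  keep <- !is.na(x)
  n_excluded <- sum(!keep)
  mut <- x[keep & patients$germline_mutant]
  wt <- x[keep & !patients$germline_mutant]
  if (length(mut) < 2 || length(wt) < 2) {
    rlang::abort(sprintf(
      "Need >= 2 patients per group (mutant %d, wild-type %d).",
      length(mut), length(wt)),
      class = "clonehet_insufficient_data")
  }
  res <- if (test_kind == "welch") welch_t(mut, wt) else student_t(mut, wt)
  structure(
    list(metric = metric,
         groups = tibble::tibble(
           group = c("mutant", "wild_type"),
           n = c(length(mut), length(wt)),
           mean = c(mean(mut), mean(wt)),
           sd = c(stats::sd(mut), stats::sd(wt))),
         t_statistic = res$t_statistic,
         df = res$df,
         p_value = res$p_value,
         test_kind = test_kind,
         n_excluded = n_excluded),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison: %s, %s t-test>\n  mutant    n=%d mean=%.4g\n  wild-type n=%d mean=%.4g\n  t = %.4g, df = %.3g, two-tailed p = %.4g\n",
    x$metric, x$test_kind, x$groups$n[1], x$groups$mean[1],
    x$groups$n[2], x$groups$mean[2], x$t_statistic, x$df, x$p_value))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d patient(s) excluded: metric undefined)\n",
                x$n_excluded))
  }
  invisible(x)
}

#' Tidy and glance methods for group comparisons
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: one row per group with `group`, `n`, `mean`, `sd`;
#'   `glance()`: one row with the test results.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$groups
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, test_kind = x$test_kind,
                 t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, n_excluded = x$n_excluded)
}
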