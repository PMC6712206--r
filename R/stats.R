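#' One-sample Z test from summary statistics
#'
#' Tests whether a population mean differs from `mu0` given the sample mean,
#' the sample standard deviation and the sample size:
#' `z = (mean - mu0) / (sd / sqrt(n))`, two-sided
#' `p = 2 * (1 - pnorm(|z|))`. This is the test applied to per-cell
#' summation scale factors against the linear-summation value 1, with the
#' sample SD of the scale factors as the dispersion.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (> 0).
#' @param n sample size (>= 2).
#' @param mu0 null-hypothesis mean, default 1.
#' @return Object of class `"ei_test"`: `statistic`, `p_value`, `n`,
#'   `test_name`, `two_sided`.
#' @examples
#' one_sample_z_test(0.91, 0.1625, 28)   # p ~ 0.0035
#' @export
one_sample_z_test <- function(mean, sd, n, mu0 = 1) {
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2", call. = FALSE)
  z <- (mean - mu0) / (sd / sqrt(n))
  ei_test(z, 2 * stats::pnorm(-abs(z)), n, "one-sample Z test")
}

ei_test <- function(statistic, p_value, n, test_name, two_sided = TRUE,
                    degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 test_name = test_name, two_sided = two_sided,
                 degenerate = degenerate),
            class = "ei_test")
}

#' @export
print.ei_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (isTRUE(x$degenerate)) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Student's t test (paired or two-sample)
#'
#' Pairwise comparisons use the paired Student t test; independent groups use
#' the classic equal-variance (pooled) two-sample form. Degenerate paired
#' input is handled explicitly: identical samples give `t = 0, p = 1`, and a
#' nonzero constant difference (zero variance) gives `p = 0` with a
#' degenerate flag.
#'
#' @param x,y numeric samples (`n >= 2`; equal lengths when paired).
#' @param paired paired test? Default `FALSE`.
#' @return Object of class `"ei_test"`.
#' @export
ei_t_test <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  if (paired) {
    if (length(x) != length(y))
      stop("paired samples must have equal length", call. = FALSE)
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(ei_test(0, 1, length(x), "paired Student t test",
                       degenerate = TRUE))
      return(ei_test(sign(mean(d)) * Inf, 0, length(x),
                     "paired Student t test", degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    return(ei_test(unname(tt$statistic), tt$p.value, length(x),
                   "paired Student t test"))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(ei_test(0, 1, c(length(x), length(y)),
                     "two-sample Student t test", degenerate = TRUE))
    return(ei_test(sign(mean(x) - mean(y)) * Inf, 0,
                   c(length(x), length(y)), "two-sample Student t test",
                   degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  ei_test(unname(tt$statistic), tt$p.value, c(length(x), length(y)),
          "two-sample Student t test")
}

#' Pearson skewness coefficient
#'
#' Characterises the asymmetry of a distribution. The default is the
#' Fisher-Pearson moment coefficient `g1 = m3 / m2^(3/2)` with population
#' moments `m_k = mean((x - mean(x))^k)`. `type = "median"` gives Pearson's
#' second (median-based) coefficient `3 (mean - median) / sd` as an
#' alternative, since the printed values in the literature do not pin down
#' the variant.
#'
#' @param x numeric sample, `n >= 3`, nonzero variance.
#' @param type `"moment"` (default) or `"median"`.
#' @return Skewness coefficient (dimensionless).
#' @export
pearson_skewness <- function(x, type = c("moment", "median")) {
  type <- match.arg(type)
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  m <- mean(x)
  if (type == "moment") {
    m2 <- mean((x - m)^2)
    if (m2 == 0) stop("zero variance: skewness undefined", call. = FALSE)
    mean((x - m)^3) / m2^1.5
  } else {
    s <- stats::sd(x)
    if (s == 0) stop("zero variance: skewness undefined", call. = FALSE)
    3 * (m - stats::median(x)) / s
  }
}

#' Pointwise significance mask between two sets of traces
#'
#' Runs a paired Student t test independently at every timepoint between two
#' matched sets of traces (e.g. DUO- versus AiP-evoked conductances across
#' cells) and returns the timepoints where `p < alpha`. No multiple-testing
#' correction is applied: the mask reports per-timepoint `p < 0.05` exactly
#' as in the figure conventions it mirrors.
#'
#' @param traces_a,traces_b numeric matrices, traces in rows (n_traces x
#'   n_samples), equal dimensions; rows are paired.
#' @param alpha significance level, default 0.05.
#' @return Logical vector (length `n_samples`): `TRUE` where `p < alpha`.
#' @export
pointwise_comparison <- function(traces_a, traces_b, alpha = 0.05) {
  traces_a <- as.matrix(traces_a); traces_b <- as.matrix(traces_b)
  if (!all(dim(traces_a) == dim(traces_b)))
    stop("trace sets must have identical dimensions", call. = FALSE)
  n <- nrow(traces_a)
  if (n < 2L) stop("need >= 2 traces per set", call. = FALSE)
  d <- traces_a - traces_b
  dm <- colMeans(d)
  dsd <- apply(d, 2, stats::sd)
  tstat <- ifelse(dsd > 0, dm / (dsd / sqrt(n)),
                  ifelse(dm == 0, 0, Inf * sign(dm)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[dsd == 0 & dm == 0] <- 1
  p[dsd == 0 & dm != 0] <- 0
  p < alpha
}
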