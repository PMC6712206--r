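#' Exponential temporal weights for the summation fit
#'
#' The scale-factor fit emphasises the early response: residuals are weighted
#' by `w(t) = exp(-t / tau)` for timepoints inside the fit window and 0
#' outside, so that with the default `tau = 20` ms most of the weight falls
#' in the first 40 ms after the stimulus.
#'
#' @param tb a [timebase()].
#' @param tau_ms weighting time constant in ms (> 0), default 20.
#' @param window_ms fit window `c(start, end)` in ms, default `c(0, 100)`.
#' @return Numeric weight vector, one entry per sample of `tb`.
#' @export
exponential_weights <- function(tb, tau_ms = 20, window_ms = c(0, 100)) {
  stopifnot(inherits(tb, "timebase"))
  if (!is.finite(tau_ms) || tau_ms <= 0)
    stop("'tau_ms' must be > 0", call. = FALSE)
  t <- tb_times(tb)
  w <- ifelse(t >= window_ms[1] - 1e-9 & t <= window_ms[2] + 1e-9 & t >= 0,
              exp(-pmax(t, 0) / tau_ms), 0)
  w
}

as_trace <- function(x, timebase = NULL) {
  if (inherits(x, "ei_sweep")) return(list(v = x$values, tb = x$timebase))
  if (is.numeric(x)) {
    if (is.null(timebase))
      stop("numeric traces need an explicit 'timebase'", call. = FALSE)
    if (length(x) != timebase$n_samples)
      stop("trace length does not match the timebase", call. = FALSE)
    return(list(v = as.numeric(x), tb = timebase))
  }
  stop("traces must be numeric vectors or ei_sweep objects", call. = FALSE)
}

#' Fit the summation scale factor of two converging inputs
#'
#' Quantifies how responses to two individually stimulated pathways combine
#' when stimulated together: the arithmetic sum of the two single-pathway
#' responses is fitted onto the simultaneous (DUO) response by one scale
#' factor, `DUO(t) ~ alpha * (AiP(t) + LA(t))`. The weighted least-squares
#' problem
#' \deqn{\alpha = \arg\min_{\alpha \ge 0} \sum_t w(t)^2 (d(t) - \alpha s(t))^2}
#' with `s = aip + la` and exponential weights [exponential_weights()] has
#' the closed form `alpha = max(0, sum(w^2 s d) / sum(w^2 s^2))` — the
#' one-variable non-negative least-squares solution. `alpha < 1` means the
#' simultaneous response is smaller than the sum of its parts (sub-linear
#' summation), `alpha = 1` linear, `alpha > 1` super-linear.
#'
#' The same fit applies to any response trace: decomposed conductances,
#' synaptic currents, or postsynaptic potentials.
#'
#' @param duo,aip,la response traces sharing one timebase ([ei_sweep()]
#'   objects or numeric vectors with `timebase` supplied).
#' @param timebase required when the traces are bare numeric vectors.
#' @param tau_ms weighting time constant (ms), default 20.
#' @param window_ms fit window, default `c(0, 100)` ms.
#' @param nonnegative constrain `alpha >= 0` (default); `FALSE` gives the
#'   unconstrained weighted least-squares solution.
#' @param tol classification tolerance around 1 passed to
#'   [classify_summation()].
#' @return Object of class `"summation_fit"`: `alpha`, `weighted_rss`,
#'   `classification`, `n_points`, `tau_ms`, `window_ms`, `nonnegative`.
#'   Methods: `print`, `summary`, `coef`.
#' @examples
#' tb <- timebase(0, 0.1, 1000)
#' a <- exp(-tb_times(tb) / 10); l <- 0.5 * a
#' fit_scale_factor(0.77 * (a + l), a, l, timebase = tb)
#' @export
fit_scale_factor <- function(duo, aip, la, timebase = NULL, tau_ms = 20,
                             window_ms = c(0, 100), nonnegative = TRUE,
                             tol = 0) {
  d <- as_trace(duo, timebase)
  a <- as_trace(aip, timebase)
  l <- as_trace(la, timebase)
  if (!same_timebase(d$tb, a$tb) || !same_timebase(d$tb, l$tb))
    stop("duo, aip and la must share one timebase", call. = FALSE)
  w <- exponential_weights(d$tb, tau_ms, window_ms)
  keep <- w > 0
  if (!any(keep)) stop("fit window contains no samples", call. = FALSE)
  w2 <- w[keep]^2
  s <- a$v[keep] + l$v[keep]
  dd <- d$v[keep]
  denom <- sum(w2 * s^2)
  if (denom <= 0)
    stop("summed single responses are identically zero in the fit window",
         call. = FALSE)
  alpha <- sum(w2 * s * dd) / denom
  if (nonnegative) alpha <- max(0, alpha)
  rss <- sum(w2 * (dd - alpha * s)^2)
  structure(list(alpha = alpha, weighted_rss = rss,
                 classification = classify_summation(alpha, tol),
                 n_points = sum(keep), tau_ms = tau_ms,
                 window_ms = window_ms, nonnegative = nonnegative),
            class = "summation_fit")
}

#' @export
print.summation_fit <- function(x, ...) {
  cat(sprintf(
    "Summation fit: alpha = %.4f (%s), weighted RSS = %.4g, %d points, tau = %g ms\n",
    x$alpha, x$classification, x$weighted_rss, x$n_points, x$tau_ms))
  invisible(x)
}

#' @export
coef.summation_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
summary.summation_fit <- function(object, ...) {
  cat(sprintf("DUO = alpha * (AiP + LA), alpha fitted by %sweighted NNLS\n",
              if (object$nonnegative) "" else "unconstrained "))
  print(object)
  invisible(object)
}

#' Classify a summation scale factor
#'
#' @param alpha fitted scale factor.
#' @param tol tolerance around 1 (default 0: strict inequalities decide).
#' @return `"superlinear"` if `alpha > 1 + tol`, `"sublinear"` if
#'   `alpha < 1 - tol`, otherwise `"linear"`.
#' @export
classify_summation <- function(alpha, tol = 0) {
  if (tol < 0) stop("'tol' must be >= 0", call. = FALSE)
  if (alpha > 1 + tol) "superlinear"
  else if (alpha < 1 - tol) "sublinear"
  else "linear"
}

#' Population summary of per-cell scale factors
#'
#' Mean, SEM (`sd / sqrt(n)`, sample SD with the n-1 denominator) and
#' Fisher-Pearson moment skewness of a set of per-cell scale factors, the
#' quantities reported for summation populations (mean +/- SEM, with the SD
#' entering the one-sample Z test against 1).
#'
#' @param alphas numeric vector of per-cell scale factors, `n >= 2`.
#' @return Named list `mean`, `sem`, `sd`, `skewness`, `n`.
#' @export
population_scale_summary <- function(alphas) {
  alphas <- as.numeric(alphas)
  n <- length(alphas)
  if (n < 2L) stop("need at least 2 scale factors", call. = FALSE)
  s <- stats::sd(alphas)
  list(mean = mean(alphas), sem = s / sqrt(n), sd = s,
       skewness = if (n >= 3L && s > 0) pearson_skewness(alphas) else NA_real_,
       n = n)
}
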