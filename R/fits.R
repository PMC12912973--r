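#' Fit an exponential distribution to durations or step sizes
#'
#' Dwell times, step times and step sizes all follow exponential
#' distributions, `N = A * exp(-t / tau)`. Two fitting routes are provided:
#' `"mle"`, for which the maximum-likelihood estimate of the mean `tau` is the
#' arithmetic mean of the observations (with an exact chi-square confidence
#' interval), and `"histogram_lsq"`, the display-style least-squares fit of
#' `A * exp(-t / tau)` to binned counts.
#'
#' @param values Positive durations (s) or sizes (nm).
#' @param method `"mle"` (default) or `"histogram_lsq"`.
#' @param bin_width Bin width for the histogram method (default 10, intended
#'   for durations in seconds; use about 5 for step sizes in nm).
#' @return An object of class `exponential_fit`: list with `tau`, `A`
#'   (histogram method only), `n`, `method` and `ci95` for `tau`.
#' @examples
#' fit_exponential(c(10, 10, 10))$tau  # 10
#' @export
fit_exponential <- function(values, method = c("mle", "histogram_lsq"),
                            bin_width = 10) {
  method <- match.arg(method)
  if (!is.numeric(values) || length(values) < 2L)
    stop_rk("need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_rk("all values must be positive and finite")
  n <- length(values)
  if (method == "mle") {
    tau <- mean(values)
    ci <- c(2 * n * tau / qchisq(0.975, 2 * n),
            2 * n * tau / qchisq(0.025, 2 * n))
    out <- list(tau = tau, A = NA_real_, n = n, method = method, ci95 = ci)
  } else {
    check_number(bin_width, "bin_width", 0, allow_lower = FALSE)
    breaks <- seq(0, max(values) + bin_width, by = bin_width)
    counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1L)
    centers <- head(breaks, -1L) + bin_width / 2
    hf <- fit_exp_histogram(centers, counts)
    out <- list(tau = hf$tau, A = hf$A, n = n, method = method,
                ci95 = c(NA_real_, NA_real_))
  }
  structure(out, class = "exponential_fit")
}

#' Least-squares exponential fit to binned counts
#'
#' Fits `N(t) = A * exp(-t / tau)` to pre-binned counts, as drawn through
#' histograms in kinetics figures. A log-linear regression on the positive
#' counts provides starting values (and is exact for noiseless exponential
#' counts); a nonlinear least-squares refinement on the count scale follows.
#'
#' @param centers Bin centers.
#' @param counts Nonnegative counts per bin.
#' @return List with `tau` and `A`.
#' @export
fit_exp_histogram <- function(centers, counts) {
  if (length(centers) != length(counts) || length(centers) < 2L)
    stop_rk("'centers' and 'counts' must be equal-length vectors (>= 2)")
  if (any(counts < 0)) stop_rk("counts must be nonnegative")
  pos <- counts > 0
  if (sum(pos) < 2L) stop_rk("need at least 2 positive counts", class = "fit")
  ll <- lm(log(counts[pos]) ~ centers[pos])
  slope <- coef(ll)[[2L]]
  if (!is.finite(slope) || slope >= 0)
    stop_rk("counts do not decay; exponential fit failed", class = "fit")
  tau0 <- -1 / slope
  A0 <- exp(coef(ll)[[1L]])
  fit <- tryCatch(
    nls(counts ~ A * exp(-centers / tau), start = list(A = A0, tau = tau0)),
    error = function(e) NULL)
  if (is.null(fit)) list(tau = tau0, A = A0)
  else list(tau = coef(fit)[["tau"]], A = coef(fit)[["A"]])
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("<exponential_fit> tau = %.4g (n = %d, %s)", x$tau, x$n, x$method))
  if (all(is.finite(x$ci95))) cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Fit a sigmoid and return its plateau
#'
#' Fits a four-parameter logistic
#' `h(t) = d + (a - d) / (1 + exp(-(t - t0) / b))` by least squares and
#' returns the upper asymptote, the plateau height a converting precursor
#' reaches. A constant trace is handled as a degenerate fit whose plateau is
#' the constant value.
#'
#' @param trace A `height_trace` (or list with `times` and `heights`).
#' @return List of class `sigmoid_fit` with `plateau`, `coefficients`,
#'   `converged` and `degenerate`.
#' @export
fit_sigmoid_plateau <- function(trace) {
  t <- trace$times; h <- trace$heights
  if (!is.numeric(t) || !is.numeric(h) || length(t) != length(h))
    stop_rk("'trace' must carry numeric 'times' and 'heights' of equal length")
  if (length(t) < 5L) stop_rk("need at least 5 samples")
  if (any(!is.finite(t)) || any(!is.finite(h))) stop_rk("values must be finite")

  if (diff(range(h)) < 1e-10 * max(1, abs(h[1]))) {
    return(structure(list(plateau = h[1],
                          coefficients = c(a = h[1], d = h[1], t0 = NA, b = NA),
                          converged = TRUE, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  nlo <- max(3L, round(length(h) * 0.15))
  d0 <- mean(head(h, nlo)); a0 <- mean(tail(h, nlo))
  t00 <- t[which.min(abs(h - (a0 + d0) / 2))]
  b0 <- diff(range(t)) / 10
  obj <- function(p) sum((h - (p[2] + (p[1] - p[2]) /
                                 (1 + exp(-(t - p[3]) / p[4]))))^2)
  fit <- tryCatch(
    nls(h ~ d + (a - d) / (1 + exp(-(t - t0) / b)),
        start = list(a = a0, d = d0, t0 = t00, b = b0)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    conv <- TRUE
  } else {
    op <- optim(c(a0, d0, t00, b0), obj, control = list(maxit = 2000))
    cf <- setNames(op$par, c("a", "d", "t0", "b"))
    conv <- op$convergence == 0
    if (!conv)
      stop_rk("sigmoid fit did not converge (SSE %.4g after optim fallback)",
              class = "fit", op$value)
  }
  # with b < 0 the roles of the asymptotes swap; the plateau is the t -> Inf limit
  plateau <- if (cf[["b"]] >= 0) cf[["a"]] else cf[["d"]]
  structure(list(plateau = plateau, coefficients = cf, converged = conv,
                 degenerate = FALSE),
            class = "sigmoid_fit")
}

#' Mean height inside a time window
#'
#' Arithmetic mean of the trace heights with `t0 <= t <= t1`, the summary used
#' for non-converting spheres (window 1600-1800 s in the original measurements).
#'
#' @param trace A `height_trace`.
#' @param t0,t1 Window bounds (s).
#' @return Mean height (nm).
#' @export
mean_window_height <- function(trace, t0, t1) {
  check_number(t0, "t0"); check_number(t1, "t1")
  if (t1 < t0) stop_rk("'t1' must be >= 't0'")
  sel <- trace$times >= t0 & trace$times <= t1
  if (!any(sel)) stop_rk("window [%g, %g] does not overlap the trace", t0, t1)
  mean(trace$heights[sel])
}
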