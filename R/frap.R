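#' Single-exponential FRAP recovery model
#'
#' `f(t) = a * (1 - exp(-b * t))`: `a` is the recovery plateau (mobile
#' fraction proxy) and `b` the exchange rate constant in 1/s.  Half-maximal
#' recovery occurs at `tau_half = ln(2) / b`.
#'
#' @param t Time since bleach, seconds (>= 0).
#' @param a Plateau (dimensionless).
#' @param b Rate constant (1/s).
#' @return Model intensity.
#' @export
frap_model <- function(t, a, b) a * (1 - exp(-b * t))

#' FRAP recovery trace
#'
#' @param times Seconds since the bleach, strictly increasing, starting at 0.
#' @param intensity Normalized recovery values (fraction of the bleached
#'   amount recovered).
#' @return A `frap_trace` data frame with columns `time_s, intensity`.
#' @export
frap_trace <- function(times, intensity) {
  if (length(times) != length(intensity)) {
    stop("times and intensity must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("times must start at or after the bleach (t >= 0)")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(data.frame(time_s = as.numeric(times),
                       intensity = as.numeric(intensity)),
            class = c("frap_trace", "data.frame"))
}

#' Normalize a raw recovery trace to the extent of bleaching
#'
#' `intensity(t) = (raw(t) - postbleach) / (prebleach - postbleach)`, with
#' time re-zeroed at the first post-bleach sample, so 0 is the bleached
#' level and 1 full recovery to the pre-bleach level.  Invariant under
#' affine rescaling of the raw signal when the reference levels are
#' rescaled alongside.
#'
#' @param times Acquisition times of the post-bleach samples, seconds.
#' @param raw_intensity Raw fluorescence values (arbitrary units).
#' @param prebleach_level,postbleach_level Reference levels in the same
#'   units; prebleach must exceed postbleach.
#' @return A [frap_trace()].
#' @export
normalize_trace <- function(times, raw_intensity, prebleach_level,
                            postbleach_level) {
  if (prebleach_level <= postbleach_level) {
    stop("prebleach_level must exceed postbleach_level")
  }
  frap_trace(times - times[1],
             (raw_intensity - postbleach_level) /
               (prebleach_level - postbleach_level))
}

#' Fit the recovery model to a trace
#'
#' Levenberg-Marquardt nonlinear least squares of [frap_model()].  The
#' default initialization takes `a0` from the last intensity sample and
#' `b0 = ln(2) / t_half_obs` from the first time the trace reaches half of
#' `a0` (falling back to `1 / max(t)`).
#'
#' @param trace A [frap_trace()] (>= 4 points, not all equal).
#' @param init Optional named vector/list `c(a=, b=)` overriding the
#'   heuristic start.
#' @return A `frap_fit`: `a`, `b`, `tau_half = ln(2)/b`, `residual_sse`,
#'   `converged`.
#' @export
fit_frap <- function(trace, init = NULL) {
  if (nrow(trace) < 4L) stop("need at least 4 points to fit the recovery model")
  y <- trace$intensity
  t <- trace$time_s
  if (diff(range(y)) == 0) {
    stop("degenerate input: constant intensity trace")
  }
  if (is.null(init)) {
    a0 <- y[length(y)]
    if (a0 <= 0) a0 <- max(y)
    if (a0 <= 0) stop("degenerate input: no positive recovery signal")
    ih <- which(y >= a0 / 2)[1]
    b0 <- if (!is.na(ih) && t[ih] > 0) log(2) / t[ih] else 1 / max(t)
    init <- c(a = a0, b = b0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ a * (1 - exp(-b * time_s)),
                      data = trace, start = as.list(init),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("FRAP fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  if (est[["b"]] <= 0) {
    stop("degenerate fit: non-positive rate constant b")
  }
  structure(list(a = unname(est[["a"]]), b = unname(est[["b"]]),
                 tau_half = log(2) / est[["b"]],
                 residual_sse = sum(resid(fit)^2),
                 converged = fit$convInfo$isConv),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> a = %.4g, b = %.4g /s, tau_half = %.4g s (SSE %.3g, %s)\n",
    x$a, x$b, x$tau_half, x$residual_sse,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarize tau-half across a set of fits
#'
#' Mean and standard error of the half-maximal recovery time across
#' converged fits, mirroring the per-component summary of FRAP experiments.
#'
#' @param fits List of [fit_frap()] results.
#' @return One-row data frame `n, mean_tau_half_s, sem_tau_half_s`.
#' @export
summarize_frap_fits <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tau <- vapply(fits[ok], `[[`, numeric(1), "tau_half")
  data.frame(n = length(tau), mean_tau_half_s = mean(tau),
             sem_tau_half_s = if (length(tau) > 1) sd(tau) / sqrt(length(tau))
                              else NA_real_)
}
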