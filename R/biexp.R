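#' @importFrom stats median optim quantile rbinom rlnorm runif setNames
#' @importFrom stats binomial coef glm integrate predict sd var wilcox.test cor.test
NULL

#' Physical half-life of 177Lu in hours
#'
#' The radionuclide's physical half-life. The washout half-time of a fitted
#' clearance curve cannot exceed this value: effective clearance includes
#' physical decay, so apparent retention slower than physical decay can only
#' arise from measurement error.
#' @export
LU177_HALFLIFE_H <- 159.5

#' Physical decay constant of 177Lu (1/h)
#' @rdname LU177_HALFLIFE_H
#' @export
LU177_LAMBDA_PHYS <- log(2) / 159.5

lutadose_input_error <- function(msg) {
  stop(errorCondition(msg, class = c("lutadose_input_error", "lutadose_error")))
}
lutadose_fit_error <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("lutadose_fit_error", "lutadose_error")))
}
lutadose_config_error <- function(msg) {
  stop(errorCondition(msg, class = c("lutadose_config_error", "lutadose_error")))
}

#' Biexponential absorbed-dose-rate model
#'
#' Evaluates the clearance model
#' \deqn{\dot D(t) = A\,(e^{-\lambda_1 t} - e^{-\lambda_2 t})}
#' where \eqn{\lambda_1} is the washout rate, \eqn{\lambda_2 > \lambda_1} the
#' uptake rate and \eqn{A} a shared amplitude, so the curve rises from zero,
#' peaks, and decays at rate \eqn{\lambda_1}.
#'
#' @param t time after injection, hours.
#' @param A amplitude, Gy/h.
#' @param lambda1 washout rate, 1/h.
#' @param lambda2 uptake rate, 1/h; must exceed `lambda1`.
#' @return dose rate in Gy/h at each `t`.
#' @export
biexp_doserate <- function(t, A, lambda1, lambda2) {
  A * (exp(-lambda1 * t) - exp(-lambda2 * t))
}

new_biexp_params <- function(A, lambda1, lambda2, clamped, residual_sse,
                             n_samples = NA_integer_) {
  structure(
    list(A = A, lambda1 = lambda1, lambda2 = lambda2,
         ad_gy = A * (1 / lambda1 - 1 / lambda2),
         clamped = clamped, residual_sse = residual_sse,
         n_samples = n_samples),
    class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  ht <- half_times(x)
  cat("Biexponential dose-rate fit\n")
  cat(sprintf("  A        : %.4g Gy/h\n", x$A))
  cat(sprintf("  washout  : t1/2 = %.4g h (lambda1 = %.4g /h)%s\n",
              ht[["washout_h"]], x$lambda1,
              if (isTRUE(x$clamped)) "  [clamped to 177Lu physical decay]" else ""))
  cat(sprintf("  uptake   : t1/2 = %.4g h (lambda2 = %.4g /h)\n",
              ht[["uptake_h"]], x$lambda2))
  cat(sprintf("  AD       : %.4g Gy\n", x$ad_gy))
  cat(sprintf("  SSE      : %.4g (Gy/h)^2 over %s samples\n",
              x$residual_sse, x$n_samples))
  invisible(x)
}

# Optimal amplitude for fixed rates (A enters the model linearly).
profile_amplitude <- function(t, y, lambda1, lambda2) {
  f <- exp(-lambda1 * t) - exp(-lambda2 * t)
  denom <- sum(f * f)
  if (denom <= 0) return(list(A = NA_real_, sse = Inf, f = f))
  A <- sum(y * f) / denom
  if (!is.finite(A) || A <= 0) return(list(A = NA_real_, sse = Inf, f = f))
  list(A = A, sse = sum((A * f - y)^2), f = f)
}

# Variable-projection Levenberg-Marquardt over reparameterised rates.
# theta -> (lambda1, lambda2): lambda1 = lambda_floor + exp(theta[1]) when
# floored (constrained refit) is FALSE lambda_floor = 0; lambda2 = lambda1 +
# exp(theta[2]).  When fix_lambda1 is set only theta[2] is optimised.
biexp_lm <- function(t, y, theta0, lambda_floor = 0, fix_lambda1 = NULL) {
  rates <- function(theta) {
    if (is.null(fix_lambda1)) {
      l1 <- lambda_floor + exp(theta[1])
      l2 <- l1 + exp(theta[2])
    } else {
      l1 <- fix_lambda1
      l2 <- l1 + exp(theta[1])
    }
    c(l1, l2)
  }
  resid_fn <- function(theta) {
    l <- rates(theta)
    pr <- profile_amplitude(t, y, l[1], l[2])
    if (!is.finite(pr$sse)) return(rep(sqrt(.Machine$double.xmax / length(y)), length(y)))
    pr$A * pr$f - y
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-15, ptol = 1e-15,
                              gtol = 0))
  l <- rates(fit$par)
  pr <- profile_amplitude(t, y, l[1], l[2])
  list(lambda1 = l[1], lambda2 = l[2], A = pr$A, sse = pr$sse,
       info = fit$info, message = fit$message)
}

#' Fit the constrained biexponential clearance model
#'
#' Least-squares fit of [biexp_doserate()] to timed dose-rate samples of one
#' structure in one treatment cycle, under the physical constraint that the
#' washout half-time be no longer than the 177Lu physical half-life (159.5 h)
#' and the ordering constraint \eqn{\lambda_2 > \lambda_1}.
#'
#' The amplitude is profiled out analytically (it enters the model linearly)
#' and the two rates are optimised by Levenberg-Marquardt from several
#' starting points; the starting washout rate comes from the log-linear slope
#' of the last two samples. The unconstrained optimum is located first; iff
#' its washout half-time exceeds 159.5 h the fit is repeated with the washout
#' rate fixed at the physical decay constant and the result is flagged
#' `clamped`. If the last two samples are non-decreasing there is no washout
#' signal in the data at all; the fit then falls back directly to the clamped
#' model.
#'
#' @param time_h sample times in hours (strictly positive, at least 3
#'   distinct), or a data.frame with columns `time_h` and `doserate`.
#' @param doserate measured dose rates in Gy/h (strictly positive).
#' @return an object of class `biexp_params`: a list with elements `A` (Gy/h),
#'   `lambda1`, `lambda2` (1/h), `ad_gy` (time-integrated absorbed dose, Gy),
#'   `clamped` (logical), `residual_sse` ((Gy/h)^2) and `n_samples`.
#' @examples
#' t <- c(4, 24, 72)
#' y <- biexp_doserate(t, A = 1, lambda1 = log(2) / 79.5, lambda2 = log(2) / 6)
#' fit_biexponential(t, y)
#' @export
fit_biexponential <- function(time_h, doserate) {
  if (is.data.frame(time_h)) {
    doserate <- time_h$doserate
    time_h <- time_h$time_h
  }
  if (length(time_h) != length(doserate))
    lutadose_input_error("time_h and doserate must have equal length")
  ok <- is.finite(time_h) & is.finite(doserate)
  if (!all(ok))
    lutadose_input_error("non-finite values in dose-rate samples")
  if (length(unique(time_h)) < 3)
    lutadose_input_error("at least 3 samples at distinct times are required")
  if (any(time_h <= 0))
    lutadose_input_error("sample times must be positive")
  if (any(doserate <= 0))
    lutadose_input_error("all dose rates must be strictly positive")

  ord <- order(time_h)
  t <- time_h[ord]
  y <- doserate[ord]
  n <- length(t)
  lphys <- LU177_LAMBDA_PHYS

  # Washout starting value from the log-linear slope of the last two
  # samples; a non-decreasing tail carries no washout signal of its own (the
  # curve may still be near its peak), so fall back to the physical decay
  # constant as the starting point and let the optimiser decide.
  tail_slope <- (log(y[n - 1]) - log(y[n])) / (t[n] - t[n - 1])
  l1_init <- if (is.finite(tail_slope) && tail_slope > 0)
    min(max(tail_slope, lphys / 10), 20) else lphys
  starts <- c(
    lapply(c(3, 5, 10, 30), function(m) c(log(l1_init), log(l1_init * (m - 1)))),
    lapply(c(5, 30), function(m) c(log(l1_init / 3), log(l1_init / 3 * (m - 1)))))
  fits <- lapply(starts, function(s) try(biexp_lm(t, y, s), silent = TRUE))
  fits <- Filter(function(f) !inherits(f, "try-error") && is.finite(f$sse), fits)
  if (length(fits) == 0)
    lutadose_fit_error("biexponential fit failed to converge from all starts",
                       diagnostics = list(time_h = t, doserate = y))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]

  if (best$lambda1 >= lphys) {
    return(new_biexp_params(best$A, best$lambda1, best$lambda2, FALSE,
                            best$sse, n))
  }
  # Unconstrained optimum decays slower than physical decay: clamp.
  fit <- fit_biexp_clamped(t, y)
  new_biexp_params(fit$A, lphys, fit$lambda2, TRUE, fit$sse, n)
}

# Washout fixed at the physical decay constant; fit amplitude + uptake rate.
fit_biexp_clamped <- function(t, y) {
  lphys <- LU177_LAMBDA_PHYS
  starts <- lapply(log(lphys * c(2, 5, 20, 100)), function(s) s)
  fits <- lapply(starts, function(s)
    try(biexp_lm(t, y, c(s), fix_lambda1 = lphys), silent = TRUE))
  fits <- Filter(function(f) !inherits(f, "try-error") && is.finite(f$sse), fits)
  if (length(fits) == 0)
    lutadose_fit_error("clamped biexponential fit failed to converge",
                       diagnostics = list(time_h = t, doserate = y))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
}

#' Time-integrated absorbed dose of a biexponential fit
#'
#' Closed-form integral of the clearance model over all time:
#' \eqn{\int_0^\infty \dot D(t)\,dt = A(1/\lambda_1 - 1/\lambda_2)}.
#'
#' @param params a `biexp_params` object, or a list with elements `A`,
#'   `lambda1`, `lambda2`.
#' @return absorbed dose in Gy.
#' @export
integrate_dose <- function(params) {
  if (params$lambda2 <= params$lambda1)
    lutadose_input_error("lambda2 must exceed lambda1 (uptake faster than washout)")
  if (params$lambda1 <= 0)
    lutadose_input_error("lambda1 must be positive")
  params$A * (1 / params$lambda1 - 1 / params$lambda2)
}

#' Washout and uptake half-times of a biexponential fit
#'
#' @param params a `biexp_params` object (or list with `lambda1`, `lambda2`).
#' @return named numeric vector `c(washout_h, uptake_h)` with
#'   `washout_h = ln 2 / lambda1` and `uptake_h = ln 2 / lambda2`.
#' @export
half_times <- function(params) {
  c(washout_h = log(2) / params$lambda1, uptake_h = log(2) / params$lambda2)
}
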