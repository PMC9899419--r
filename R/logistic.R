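# Logistic accumulation kinetics: W(x) = a / (1 + exp(-k (x - x_c))).
# The accumulation rate is the first derivative a k p (1 - p) with
# p = plogis(k (x - x_c)); it peaks at x = x_c with value a k / 4.

#' Logistic content curve
#'
#' @param x DAF values.
#' @param a Asymptotic content (content units per grain).
#' @param k Exponential growth rate (per day), > 0.
#' @param x_c Inflection time (DAF) at which content reaches `a / 2`.
#' @return Content at `x`.
#' @export
logistic_value <- function(x, a, k, x_c) {
  a * stats::plogis(k * (x - x_c))
}

#' Logistic accumulation rate (first derivative of the content curve)
#'
#' @inheritParams logistic_value
#' @return Rate at `x`, in content units per day.
#' @export
logistic_rate <- function(x, a, k, x_c) {
  p <- stats::plogis(k * (x - x_c))
  a * k * p * (1 - p)
}

#' Options for the logistic fit
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Convergence tolerance on the relative parameter change.
#' @return List of fit options.
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-10) {
  stopifnot(max_iter >= 1, tol > 0)
  list(max_iter = as.integer(max_iter), tol = tol)
}

logistic_start <- function(x, W) {
  a0 <- 1.05 * max(W)
  tm <- sort(unique(x))
  wm <- as.numeric(tapply(W, x, mean)[as.character(tm)])
  half <- a0 / 2
  nt <- length(tm)
  if (wm[1] >= half) {
    x_c0 <- tm[1] - 1
  } else if (all(wm < half)) {
    # inflection beyond the window: extrapolate from the last two means
    slope <- (wm[nt] - wm[nt - 1]) / (tm[nt] - tm[nt - 1])
    x_c0 <- if (is.finite(slope) && slope > 0) {
      tm[nt] + (half - wm[nt]) / slope
    } else tm[nt] + 5
  } else {
    i <- which(wm >= half)[1]
    x_c0 <- tm[i - 1] + (half - wm[i - 1]) / (wm[i] - wm[i - 1]) * (tm[i] - tm[i - 1])
  }
  p <- pmin(pmax(wm / a0, 1e-6), 1 - 1e-6)
  k0 <- tryCatch(unname(stats::coef(stats::lm(stats::qlogis(p) ~ tm))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.3
  c(a = a0, k = min(max(k0, 1e-3), 5), x_c = x_c0)
}

failed_fit <- function(series, message, n_obs = NA_integer_, data = NULL) {
  structure(list(element = series$element, tissue = series$tissue,
                 unit = series$unit, a = NA_real_, k = NA_real_, x_c = NA_real_,
                 vcov = matrix(NA_real_, 3, 3,
                               dimnames = list(c("a", "k", "x_c"), c("a", "k", "x_c"))),
                 sigma = NA_real_, r_squared = NA_real_,
                 df_residual = NA_integer_, n_obs = n_obs,
                 converged = FALSE, message = message, data = data),
            class = "logistic_fit")
}

#' Fit the logistic accumulation model to a content series
#'
#' Least-squares estimation of `(a, k, x_c)` over all replicate observations
#' by bounded Levenberg-Marquardt (via [minpack.lm::nlsLM()]).  Starting
#' values are derived from the data: `a` from 1.05 x max content, `x_c` from
#' the first half-asymptote crossing of the interpolated replicate means
#' (extrapolated when the inflection lies outside the sampling window), `k`
#' from the slope of logit(W / a0) against time.  Bounds allow the inflection
#' up to 30 days outside the window.  Non-convergence (including degenerate
#' constant series) is flagged on the returned object, never thrown.
#'
#' @param series A [grain_series()] with >= 4 distinct sampling times and at
#'   least one positive value.
#' @param options A [fit_options()] list.
#' @return Object of class `logistic_fit` with estimates, parameter
#'   covariance, residual SD, R-squared, residual df, and a convergence flag.
#' @export
fit_logistic <- function(series, options = fit_options()) {
  stopifnot(inherits(series, "grain_series"))
  obs <- series$observations
  x <- obs$daf
  W <- obs$value
  if (length(unique(x)) < 4L) {
    stop("input error: need >= 4 distinct time points to fit", call. = FALSE)
  }
  if (all(W <= 0)) {
    stop("input error: series has no positive content values", call. = FALSE)
  }
  dat <- data.frame(x = x, W = W)
  if (stats::sd(W) == 0) {
    return(failed_fit(series, "constant series: k unidentifiable", length(W), dat))
  }
  start <- logistic_start(x, W)
  lower <- c(a = 1e-12, k = 1e-6, x_c = min(x) - 30)
  upper <- c(a = 10 * max(W), k = 5, x_c = max(x) + 30)
  start <- pmin(pmax(start, lower), upper)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      W ~ a / (1 + exp(-k * (x - x_c))),
      data = dat, start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iter, ftol = options$tol, ptol = options$tol)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(failed_fit(series, conditionMessage(fit), length(W), dat))
  }
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) vc <- matrix(NA_real_, 3, 3)
  dimnames(vc) <- list(c("a", "k", "x_c"), c("a", "k", "x_c"))
  dfres <- length(W) - 3L
  dev <- stats::deviance(fit)
  structure(list(element = series$element, tissue = series$tissue,
                 unit = series$unit,
                 a = unname(co["a"]), k = unname(co["k"]), x_c = unname(co["x_c"]),
                 vcov = vc,
                 sigma = if (dfres > 0) sqrt(dev / dfres) else NA_real_,
                 r_squared = 1 - dev / sum((W - mean(W))^2),
                 df_residual = dfres, n_obs = length(W),
                 converged = isTRUE(fit$convInfo$isConv),
                 message = fit$convInfo$stopMessage, data = dat),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s (%s)\n", x$element, x$tissue))
  if (x$converged) {
    cat(sprintf("  a = %.4g %s, k = %.4g /d, x_c = %.4g DAF (R2 = %.4f, n = %d)\n",
                x$a, x$unit, x$k, x$x_c, x$r_squared, x$n_obs))
  } else {
    cat("  not converged:", x$message, "\n")
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(a = object$a, k = object$k, x_c = object$x_c)
}

#' @export
predict.logistic_fit <- function(object, x, ...) {
  if (!object$converged) stop("contract error: fit did not converge", call. = FALSE)
  logistic_value(x, object$a, object$k, object$x_c)
}

check_converged <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    stop("contract error: logistic fit did not converge", call. = FALSE)
  }
  invisible(fit)
}

#' Accumulation-rate curve of a fitted logistic model
#'
#' @param fit A converged [fit_logistic()] result.
#' @param grid DAF values at which to evaluate the rate.
#' @return Object of class `rate_curve`: the grid, rate values (content per
#'   day), and the closed-form peak location/value (`t_peak = x_c`,
#'   `peak_rate = a k / 4`).
#' @export
rate_curve <- function(fit, grid) {
  check_converged(fit)
  structure(list(element = fit$element, unit = fit$unit, x = as.numeric(grid),
                 rate = logistic_rate(grid, fit$a, fit$k, fit$x_c),
                 t_peak = fit$x_c, peak_rate = fit$a * fit$k / 4),
            class = "rate_curve")
}

#' Peak accumulation rate and its timing
#'
#' For the logistic model the rate maximum is always at the inflection point:
#' `t_peak = x_c`, `peak = a k / 4`.
#'
#' @param fit A converged [fit_logistic()] result.
#' @return List with `t_peak` (DAF) and `peak_rate` (content per day).
#' @export
peak_rate <- function(fit) {
  check_converged(fit)
  list(t_peak = fit$x_c, peak_rate = fit$a * fit$k / 4)
}

#' Pointwise confidence band for the fitted content curve
#'
#' Delta-method band: the gradient of the logistic mean with respect to
#' `(a, k, x_c)` is propagated through the parameter covariance, and the
#' standard error is scaled by the t quantile at the residual degrees of
#' freedom.  The band always contains the fitted curve and collapses to zero
#' width as the residual SD vanishes.
#'
#' @param fit A converged [fit_logistic()] result with >= 1 residual df.
#' @param grid DAF values.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return Data frame with `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, grid, level = 0.95) {
  check_converged(fit)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("parameter error: level must be in (0, 1)", call. = FALSE)
  }
  if (is.na(fit$df_residual) || fit$df_residual < 1L) {
    stop("contract error: need >= 1 residual degree of freedom", call. = FALSE)
  }
  if (anyNA(fit$vcov)) {
    stop("contract error: parameter covariance unavailable", call. = FALSE)
  }
  x <- as.numeric(grid)
  p <- stats::plogis(fit$k * (x - fit$x_c))
  G <- cbind(a = p,
             k = fit$a * (x - fit$x_c) * p * (1 - p),
             x_c = -fit$a * fit$k * p * (1 - p))
  se <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  tq <- stats::qt(1 - (1 - level) / 2, fit$df_residual)
  w <- predict(fit, x)
  data.frame(x = x, fit = w, lower = w - tq * se, upper = w + tq * se)
}
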