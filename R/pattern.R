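# Accumulation-pattern classification.  Because the logistic rate peaks at
# x_c, the early / mid / sustained distinction reduces to comparing the
# fitted inflection time with the sampling window: rate already declining at
# the first sampling time (t_peak <= t_first) is "early", still rising at the
# last (t_peak >= t_last) is "sustained", a peak inside the window is "mid".
# Boundary ties resolve to early / sustained.

PATTERNS <- c("early", "mid", "sustained")

pattern_label <- function(element, pattern, t_peak, delta, basis) {
  data.frame(element = element, pattern = pattern, t_peak = t_peak,
             delta_vs_drymatter = delta, basis = basis,
             stringsAsFactors = FALSE)
}

#' Classify an element's accumulation pattern from its logistic fit
#'
#' @param fit Converged [fit_logistic()] result for the element.
#' @param drymatter_fit Converged fit for grain dry matter; the mid-pattern
#'   timing offset `delta_vs_drymatter = t_peak(element) - t_peak(dry matter)`
#'   is reported relative to it.
#' @param window Sampling window `c(t_first, t_last)` in DAF.
#' @return One-row data frame: `element`, `pattern`, `t_peak`,
#'   `delta_vs_drymatter` (NA unless mid), `basis = "fitted"`.
#' @export
classify_pattern <- function(fit, drymatter_fit, window) {
  if (missing(drymatter_fit) || is.null(drymatter_fit)) {
    stop("contract error: dry-matter fit required", call. = FALSE)
  }
  check_converged(fit)
  check_converged(drymatter_fit)
  stopifnot(length(window) == 2L, window[1] < window[2])
  t_peak <- fit$x_c
  pattern <- if (t_peak <= window[1]) "early"
             else if (t_peak >= window[2]) "sustained"
             else "mid"
  delta <- if (pattern == "mid") t_peak - drymatter_fit$x_c else NA_real_
  pattern_label(fit$element, pattern, t_peak, delta, "fitted")
}

#' Empirical fallback classification from finite-difference rates
#'
#' Used when the logistic fit fails.  Rates between successive replicate
#' means are ranked against time with Spearman's rho: consistently falling
#' rates (rho <= -0.5) give "early", consistently rising (rho >= 0.5) give
#' "sustained", anything hump-shaped in between gives "mid".  The +/- 0.5
#' thresholds are a package choice, recorded in the `basis` column.
#'
#' @param series A [grain_series()] with >= 3 distinct sampling times.
#' @param window Sampling window `c(t_first, t_last)`.
#' @return One-row data frame as in [classify_pattern()], with
#'   `basis = "empirical-fallback"` and `t_peak` the midpoint of the interval
#'   with the largest finite-difference rate.
#' @export
classify_empirical <- function(series, window) {
  stopifnot(inherits(series, "grain_series"))
  m <- series_means(series)
  if (nrow(m) < 3L) {
    stop("input error: need >= 3 time points for empirical classification",
         call. = FALSE)
  }
  rates <- diff(m$mean) / diff(m$daf)
  mid_t <- (m$daf[-1] + m$daf[-nrow(m)]) / 2
  rho <- suppressWarnings(stats::cor(mid_t, rates, method = "spearman"))
  pattern <- if (is.na(rho)) "mid"
             else if (rho <= -0.5) "early"
             else if (rho >= 0.5) "sustained"
             else "mid"
  pattern_label(series$element, pattern, mid_t[which.max(rates)], NA_real_,
                "empirical-fallback")
}

#' Classify one element, falling back to the empirical rule if the fit failed
#'
#' @param series The element's grain [grain_series()].
#' @param fit Its [fit_logistic()] result (possibly non-converged).
#' @param drymatter_fit Converged dry-matter fit.
#' @param window Sampling window `c(t_first, t_last)`.
#' @return One-row pattern label data frame.
#' @export
classify_element <- function(series, fit, drymatter_fit, window) {
  if (inherits(fit, "logistic_fit") && isTRUE(fit$converged)) {
    classify_pattern(fit, drymatter_fit, window)
  } else {
    classify_empirical(series, window)
  }
}

#' Summarize pattern labels across a panel of elements
#'
#' @param labels Data frame of pattern labels (rows from
#'   [classify_pattern()] / [classify_empirical()], rbind-ed).
#' @return Data frame with one row per pattern (`early`, `mid`, `sustained`):
#'   the count and the comma-separated element list, elements sorted by label.
#' @export
summarize_patterns <- function(labels) {
  if (is.null(labels) || nrow(labels) < 1L) {
    stop("input error: need at least one pattern label", call. = FALSE)
  }
  out <- do.call(rbind, lapply(PATTERNS, function(p) {
    el <- sort(labels$element[labels$pattern == p])
    data.frame(pattern = p, n = length(el),
               elements = paste(el, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
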