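# Source-sink redistribution budget.  Net accumulation of tissue i over the
# filling window is dC_i = C_last,i - C_first,i; a negative dC in a
# vegetative tissue marks it as a source (elements exported towards the
# grain).  The contribution ratio R_i = |dC_i| / C_last,grain x 100% is
# computed for source tissues only; sink tissues (dC > 0) get R = 0 so that
# inflows are not counted as contributions.  "Other sources" (stem transport,
# root absorption, ...) is the remainder 100 - sum(R_i).

#' Net accumulation of an element in a tissue over the filling window
#'
#' @param c_first Content at the first sampling time (e.g. 5 DAF), >= 0.
#' @param c_last Content at the last sampling time (e.g. 30 DAF), >= 0.
#' @param unit_first,unit_last Optional content units; if both given they
#'   must agree.
#' @return Signed net accumulation `c_last - c_first` (negative = source
#'   behaviour, positive = sink behaviour).
#' @export
net_accumulation <- function(c_first, c_last, unit_first = NULL, unit_last = NULL) {
  if (!is.null(unit_first) && !is.null(unit_last)) {
    if (normalize_unit(unit_first) != normalize_unit(unit_last)) {
      stop("unit error: contents in different units (", unit_first, " vs ",
           unit_last, ")", call. = FALSE)
    }
  }
  stopifnot(c_first >= 0, c_last >= 0)
  c_last - c_first
}

#' Contribution ratio of a vegetative tissue to grain content
#'
#' @param delta_c Net accumulation of the tissue (same unit as the grain).
#' @param c_last_grain Grain content at the last sampling time, > 0.
#' @return `|delta_c| / c_last_grain * 100`, in percent.
#' @export
contribution_ratio <- function(delta_c, c_last_grain) {
  if (!is.numeric(c_last_grain) || c_last_grain <= 0) {
    stop("domain error: grain content at the final sampling time must be > 0",
         call. = FALSE)
  }
  abs(delta_c) / c_last_grain * 100
}

#' Assemble the tissue redistribution budget for one element
#'
#' Endpoint contents are replicate means at the first and last sampling times
#' (observed contents, not fitted values).  Vegetative tissues with negative
#' net accumulation are sources and receive a contribution ratio; tissues
#' with positive net accumulation are sinks with R = 0.  The remainder
#' `100 - sum(R_sources)` is attributed to other sources and floored at 0
#' (with a warning) if the summed source exports exceed the grain gain.
#'
#' @param series Named list of [grain_series()] containing at least `grain`
#'   plus vegetative tissues (typically `flag_leaf` and `node_I`), all in the
#'   same unit and each observed at both window endpoints.
#' @param window Budget window `c(t_first, t_last)` in DAF; default `c(5, 30)`.
#' @return Object of class `tissue_budget`: a data frame with one row per
#'   tissue (`element`, `tissue`, `C_first`, `C_last`, `deltaC`, `role`,
#'   `R_percent`, `other_sources_percent`).
#' @export
assemble_budget <- function(series, window = c(5, 30)) {
  stopifnot(is.list(series), length(series) >= 2L)
  tissues <- vapply(series, function(s) s$tissue, character(1))
  names(series) <- tissues
  if (!"grain" %in% tissues) {
    stop("input error: a 'grain' series is required", call. = FALSE)
  }
  units <- unique(vapply(series, function(s) s$unit, character(1)))
  if (length(units) > 1L) {
    stop("unit error: tissues measured in different units: ",
         paste(units, collapse = ", "), call. = FALSE)
  }
  element <- series$grain$element
  endpoint <- function(s, t) {
    v <- s$observations$value[s$observations$daf == t]
    if (!length(v)) {
      stop("input error: tissue '", s$tissue, "' has no observations at ",
           t, " DAF", call. = FALSE)
    }
    mean(v)
  }
  c_first <- vapply(series, endpoint, numeric(1), t = window[1])
  c_last <- vapply(series, endpoint, numeric(1), t = window[2])
  delta <- c_last - c_first
  if (c_last[["grain"]] <= 0) {
    stop("domain error: grain content at the final sampling time must be > 0",
         call. = FALSE)
  }
  veg <- setdiff(tissues, "grain")
  role <- ifelse(delta < 0, "source", "sink")
  role[["grain"]] <- "sink"
  r_pct <- stats::setNames(numeric(length(tissues)), tissues)
  for (tis in veg) {
    if (role[[tis]] == "source") {
      r_pct[[tis]] <- contribution_ratio(delta[[tis]], c_last[["grain"]])
    }
  }
  other <- 100 - sum(r_pct[veg])
  if (other < 0) {
    warning("source contributions exceed 100% of grain content at ",
            window[2], " DAF for element '", element,
            "'; other-sources remainder floored at 0", call. = FALSE)
    other <- 0
  }
  out <- data.frame(element = element, tissue = tissues,
                    C_first = as.numeric(c_first), C_last = as.numeric(c_last),
                    deltaC = as.numeric(delta), role = unname(role[tissues]),
                    R_percent = as.numeric(r_pct[tissues]),
                    other_sources_percent = other,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tissue_budget", "data.frame")
  out
}
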