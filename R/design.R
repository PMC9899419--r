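#' @keywords internal
"_PACKAGE"

# Closed set of per-grain content units.  "μg" (micro sign variants) are
# normalized to "ug" on input; units are never converted between scales.
CONTENT_UNITS <- c("mg", "ug", "ng", "pg")

normalize_unit <- function(unit) {
  u <- trimws(as.character(unit))
  gsub("µ|μ", "u", u)
}

check_unit <- function(unit) {
  u <- normalize_unit(unit)
  if (length(u) != 1L || is.na(u) || !u %in% CONTENT_UNITS) {
    stop("unit error: unit must be one of ", paste(CONTENT_UNITS, collapse = ", "),
         " (got '", unit, "')", call. = FALSE)
  }
  u
}

#' Describe a grain-development sampling design
#'
#' A study design records the sampling times (days after fertilization, DAF),
#' the replicate count per time point, the tissues sampled, and the elements
#' measured with their per-grain content units.  Downstream readers and
#' simulators validate their inputs against the design.
#'
#' @param time_points Strictly increasing integer sampling times in DAF.
#'   The default is the seven-stage grain-filling design 5, 9, 13, 17, 21,
#'   25, 30 DAF.
#' @param replicates Number of biological replicates per time point (>= 2).
#' @param tissues Character vector of tissue labels.
#' @param elements Character vector of unique element (or dry-matter) labels.
#' @param units Named character vector giving the content unit for each
#'   element, drawn from `mg`, `ug`, `ng`, `pg` (per grain).  Unnamed scalar
#'   recycles to all elements; `NULL` means `"mg"` throughout.
#'
#' @return An object of class `study_design`.
#' @examples
#' study_design(elements = c("dry_matter", "N"), units = c(dry_matter = "mg", N = "ug"))
#' @export
study_design <- function(time_points = c(5L, 9L, 13L, 17L, 21L, 25L, 30L),
                         replicates = 4L,
                         tissues = c("grain", "flag_leaf", "node_I"),
                         elements = "dry_matter",
                         units = NULL) {
  time_points <- as.integer(time_points)
  if (length(time_points) < 1L || anyNA(time_points)) {
    stop("time_points must be integer DAF values", call. = FALSE)
  }
  if (is.unsorted(time_points, strictly = TRUE)) {
    stop("time_points must be strictly increasing", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L) {
    stop("replicates must be >= 2", call. = FALSE)
  }
  elements <- as.character(elements)
  if (anyDuplicated(elements)) {
    stop("element labels must be unique", call. = FALSE)
  }
  if (is.null(units)) units <- rep("mg", length(elements))
  if (is.null(names(units))) {
    if (length(units) == 1L) units <- rep(units, length(elements))
    names(units) <- elements
  }
  units <- vapply(units[elements], check_unit, character(1))
  structure(
    list(time_points = time_points, replicates = replicates,
         tissues = as.character(tissues), elements = elements, units = units),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Grain-development study design\n")
  cat("  DAF:       ", paste(x$time_points, collapse = ", "), "\n")
  cat("  replicates:", x$replicates, "per time point\n")
  cat("  tissues:   ", paste(x$tissues, collapse = ", "), "\n")
  cat("  elements:  ", length(x$elements), "\n")
  invisible(x)
}

#' Replicated content series for one element in one tissue
#'
#' The basic container for per-grain content (or dry matter) measured across
#' DAF.  Observations are kept at replicate level; values must be
#' non-negative and share a single content unit.
#'
#' @param element Element (or `"dry_matter"`) label.
#' @param tissue Tissue label, e.g. `"grain"`, `"flag_leaf"`, `"node_I"`.
#' @param unit Content unit per grain (`mg`, `ug`, `ng`, `pg`).
#' @param observations Data frame with columns `daf`, `replicate`, `value`.
#'
#' @return An object of class `grain_series`.
#' @export
grain_series <- function(element, tissue, unit, observations) {
  unit <- check_unit(unit)
  need <- c("daf", "replicate", "value")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("schema error: observations missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  obs <- data.frame(daf = as.numeric(observations$daf),
                    replicate = as.integer(observations$replicate),
                    value = as.numeric(observations$value))
  if (nrow(obs) == 0L) stop("input error: empty observation table", call. = FALSE)
  if (anyNA(obs$value) || any(!is.finite(obs$value))) {
    stop("validation error: non-finite content values", call. = FALSE)
  }
  if (any(obs$value < 0)) {
    stop("validation error: content values must be >= 0", call. = FALSE)
  }
  obs <- obs[order(obs$daf, obs$replicate), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(element = as.character(element), tissue = as.character(tissue),
                 unit = unit, observations = obs),
            class = "grain_series")
}

#' @export
print.grain_series <- function(x, ...) {
  cat(sprintf("<grain_series> %s in %s [%s/grain], %d observations at %d DAF points\n",
              x$element, x$tissue, x$unit, nrow(x$observations),
              length(unique(x$observations$daf))))
  invisible(x)
}

#' Replicate means of a content series by sampling time
#'
#' @param series A [grain_series()].
#' @return Data frame with columns `daf` and `mean`, ordered by DAF.
#' @export
series_means <- function(series) {
  stopifnot(inherits(series, "grain_series"))
  obs <- series$observations
  m <- tapply(obs$value, obs$daf, mean)
  data.frame(daf = as.numeric(names(m)), mean = as.numeric(m))
}
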