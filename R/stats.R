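# Group statistics supporting the panicle-position and seed-setting-rate
# analyses: Z-score standardization, OLS regression with Pearson correlation
# and a t-based mean-response band, and one-way ANOVA with Tukey HSD and a
# compact letter display.

#' Z-score standardization
#'
#' `(x - mean) / SD` with the sample (n-1) SD, so the output has mean 0 and
#' SD 1.  Affine transforms of the input yield identical Z-scores.
#'
#' @param values Numeric vector with >= 2 values and non-zero SD.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("domain error: need >= 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("domain error: zero standard deviation", call. = FALSE)
  (values - mean(values)) / s
}

#' Linear regression with Pearson correlation and confidence band
#'
#' Ordinary least squares of `y` on `x` (e.g. Z-scored concentration on
#' raceme rank or seed-setting rate), with the Pearson correlation
#' coefficient, its two-sided t-test p-value, and the pointwise t-based
#' confidence band for the mean response.
#'
#' @param x Predictor (>= 3 points, not constant).
#' @param y Response, same length.
#' @param level Band coverage probability (default 0.95).
#' @param grid Values at which to evaluate the band; defaults to sorted `x`.
#' @return List: `slope`, `intercept`, `r`, `p_value`, `n`, `level`, and
#'   `band` (data frame `x`, `fit`, `lower`, `upper`).
#' @export
regress_with_ci <- function(x, y, level = 0.95, grid = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("domain error: need >= 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("domain error: x is constant", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("parameter error: level must be in (0, 1)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  p <- stats::summary.lm(fit)$coefficients["x", "Pr(>|t|)"]
  if (is.null(grid)) grid <- sort(unique(x))
  ci <- stats::predict(fit, newdata = data.frame(x = grid),
                       interval = "confidence", level = level)
  list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
       r = r, p_value = p, n = length(x), level = level,
       band = data.frame(x = grid, fit = ci[, "fit"], lower = ci[, "lwr"],
                         upper = ci[, "upr"]))
}

# Compact letter display over groups sorted by decreasing mean: maximal runs
# of mutually non-significant groups each get a letter; runs contained in an
# earlier run are absorbed.
compact_letters <- function(means, nonsig) {
  ord <- order(means, decreasing = TRUE)
  k <- length(means)
  ns <- nonsig[ord, ord, drop = FALSE]
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[i:(j + 1), i:(j + 1)])) j <- j + 1
    contained <- any(vapply(runs, function(r) i >= r[1] && j <= r[2], logical(1)))
    if (!contained) runs[[length(runs) + 1L]] <- c(i, j)
  }
  letters_out <- character(k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    letters_out[idx] <- paste0(letters_out[idx], letters[r])
  }
  out <- character(k)
  out[ord] <- letters_out
  stats::setNames(out, names(means))
}

#' One-way ANOVA with Tukey comparisons and compact letter display
#'
#' Fits a one-way ANOVA across groups, runs Tukey's HSD on all pairs at
#' `alpha`, and summarizes the pairwise decisions as letters: groups sharing
#' a letter are not significantly different.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 values).
#' @param alpha Significance level for Tukey decisions (default 0.05).
#' @return List: `means` (named group means), `anova_p` (F-test p-value),
#'   `tukey` (data frame `pair`, `diff`, `lower`, `upper`, `p_adj`), and
#'   `letters` (named compact letter display).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("input error: need >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(grepl("-", names(groups), fixed = TRUE))) {
    stop("input error: group names must not contain '-'", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop("input error: every group needs >= 2 values", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- rownames(tk)
  tukey <- data.frame(pair = pairs, diff = tk[, "diff"], lower = tk[, "lwr"],
                      upper = tk[, "upr"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  means <- vapply(groups, mean, numeric(1))
  k <- length(groups)
  nonsig <- matrix(TRUE, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(nrow(tukey))) {
    gg <- strsplit(tukey$pair[i], "-", fixed = TRUE)[[1]]
    ns <- tukey$p_adj[i] >= alpha
    nonsig[gg[1], gg[2]] <- ns
    nonsig[gg[2], gg[1]] <- ns
  }
  list(means = means, anova_p = anova_p, tukey = tukey,
       letters = compact_letters(means, nonsig))
}
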