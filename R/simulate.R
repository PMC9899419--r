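# Synthetic-data generator.  Emulates the statistical structure of a
# grain-filling study: replicated element contents on logistic trajectories
# (three timing archetypes), source/sink tissue series with known
# contribution fractions, and FPKM matrices with genes planted on integer
# temporal profiles.  Ground truth is always attached so downstream stages
# can be validated against it.

#' Define an element accumulation archetype
#'
#' An archetype is a logistic trajectory plus a timing label relative to the
#' sampling window: `early` (inflection at or before the first sampling
#' time), `mid` (inside the window), `sustained` (at or after the last).
#' Replicate noise is multiplicative lognormal with the stated coefficient
#' of variation, so simulated contents stay positive with mean on the curve.
#'
#' @param label One of `"early"`, `"mid"`, `"sustained"`.
#' @param a Asymptotic content, > 0 (content units per grain).
#' @param k Exponential growth rate, > 0 (per day).
#' @param x_c Inflection time (DAF); its position relative to the design
#'   window is checked when simulating.
#' @param noise_cv Coefficient of variation of replicate noise, >= 0.
#' @return Object of class `element_archetype`.
#' @export
element_archetype <- function(label, a, k, x_c, noise_cv = 0.1) {
  label <- match.arg(label, PATTERNS)
  if (!is.numeric(a) || a <= 0) stop("parameter error: a must be > 0", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("parameter error: k must be > 0", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("parameter error: noise_cv must be >= 0", call. = FALSE)
  }
  structure(list(label = label, a = a, k = k, x_c = x_c, noise_cv = noise_cv),
            class = "element_archetype")
}

check_archetype_window <- function(archetype, design) {
  t1 <- design$time_points[1]
  tL <- design$time_points[length(design$time_points)]
  ok <- switch(archetype$label,
               early = archetype$x_c <= t1,
               mid = archetype$x_c > t1 && archetype$x_c < tL,
               sustained = archetype$x_c >= tL)
  if (!ok) {
    stop("parameter error: archetype '", archetype$label, "' requires x_c ",
         switch(archetype$label,
                early = paste("<=", t1), mid = paste("inside (", t1, ",", tL, ")"),
                sustained = paste(">=", tL)),
         " but x_c = ", archetype$x_c, call. = FALSE)
  }
  invisible(TRUE)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a replicated content series from an archetype
#'
#' Replicate values are the logistic mean at each DAF multiplied by lognormal
#' noise with the archetype's CV.  The archetype (ground truth) is attached
#' as the `"truth"` attribute.
#'
#' @param archetype An [element_archetype()].
#' @param design A [study_design()]; its window must be consistent with the
#'   archetype label.
#' @param seed Integer RNG seed.
#' @param element,tissue,unit Labels for the generated series.
#' @return A [grain_series()] with `attr(, "truth")` set to the archetype.
#' @export
simulate_grain_series <- function(archetype, design, seed,
                                  element = "element", tissue = "grain",
                                  unit = "mg") {
  stopifnot(inherits(archetype, "element_archetype"),
            inherits(design, "study_design"))
  check_archetype_window(archetype, design)
  set.seed(seed)
  nrep <- design$replicates
  obs <- do.call(rbind, lapply(design$time_points, function(t) {
    mu <- logistic_value(t, archetype$a, archetype$k, archetype$x_c)
    data.frame(daf = t, replicate = seq_len(nrep),
               value = mu * lognormal_noise(nrep, archetype$noise_cv))
  }))
  out <- grain_series(element, tissue, unit, obs)
  attr(out, "truth") <- archetype
  out
}

#' Simulate grain, flag-leaf, and node-I series with known contribution ratios
#'
#' The grain follows the archetype's logistic trajectory.  Each vegetative
#' tissue changes linearly over the window by `-fraction x C_last,grain`,
#' where `C_last,grain` is the noise-free grain content at the last sampling
#' time -- so the downstream budget recovers exactly
#' `R(flag leaf) = 100 source_fraction`, `R(node I) = 100 node_fraction`, and
#' `other = 100 (1 - source_fraction - node_fraction)` when noise is off.  A
#' negative fraction makes the tissue gain content, i.e. behave as a sink
#' (Ca/Mn-like behaviour of the flag leaf).
#'
#' @param element Element label.
#' @param source_fraction Fraction of final grain content exported by the
#'   flag leaf, in `[-1, 1]`.
#' @param node_fraction Same for node I; `source_fraction + node_fraction`
#'   must not exceed 1.
#' @param design A [study_design()].
#' @param seed Integer RNG seed.
#' @param archetype Grain trajectory; default a mid archetype
#'   (`a = 25, k = 0.3, x_c = 15`) with no noise.
#' @param noise_cv Replicate noise CV applied to all three tissues.
#' @param unit Content unit.
#' @return Named list of three [grain_series()] (`grain`, `flag_leaf`,
#'   `node_I`) with a `"truth"` attribute recording the planted fractions.
#' @export
simulate_tissue_budget <- function(element, source_fraction, node_fraction,
                                   design, seed,
                                   archetype = element_archetype("mid", a = 25,
                                                                 k = 0.3, x_c = 15,
                                                                 noise_cv = 0),
                                   noise_cv = archetype$noise_cv, unit = "mg") {
  stopifnot(inherits(design, "study_design"))
  if (abs(source_fraction) > 1 || abs(node_fraction) > 1) {
    stop("parameter error: fractions must lie in [-1, 1]", call. = FALSE)
  }
  if (source_fraction + node_fraction > 1) {
    stop("parameter error: source_fraction + node_fraction must be <= 1",
         call. = FALSE)
  }
  check_archetype_window(archetype, design)
  set.seed(seed)
  tp <- design$time_points
  t1 <- tp[1]; tL <- tp[length(tp)]
  nrep <- design$replicates
  c_last_grain <- logistic_value(tL, archetype$a, archetype$k, archetype$x_c)
  make_series <- function(tissue, mean_fun) {
    obs <- do.call(rbind, lapply(tp, function(t) {
      data.frame(daf = t, replicate = seq_len(nrep),
                 value = mean_fun(t) * lognormal_noise(nrep, noise_cv))
    }))
    grain_series(element, tissue, unit, obs)
  }
  veg_fun <- function(fraction) {
    # linear drawdown (or gain) over the window; baseline keeps content >= 0
    baseline <- (0.5 + max(fraction, 0)) * c_last_grain
    function(t) baseline - fraction * c_last_grain * (t - t1) / (tL - t1)
  }
  out <- list(
    grain = make_series("grain", function(t)
      logistic_value(t, archetype$a, archetype$k, archetype$x_c)),
    flag_leaf = make_series("flag_leaf", veg_fun(source_fraction)),
    node_I = make_series("node_I", veg_fun(node_fraction))
  )
  attr(out, "truth") <- list(source_fraction = source_fraction,
                             node_fraction = node_fraction,
                             c_last_grain = c_last_grain)
  out
}

default_profiles <- function(n_time) {
  stopifnot(n_time >= 2)
  peak <- numeric(n_time)
  half <- ceiling(n_time / 2)
  peak[seq_len(half)] <- seq_len(half) - 1
  if (half < n_time) {
    peak[(half + 1):n_time] <- peak[half] - seq_len(n_time - half)
  }
  list(decreasing = -(seq_len(n_time) - 1),
       increasing = seq_len(n_time) - 1,
       peak = pmax(peak, 0))
}

#' Describe a planted-profile expression scenario
#'
#' @param profiles Named list of integer profile vectors (each starting at 0)
#'   on which genes are planted; `NULL` gives a monotone-decreasing, a
#'   monotone-increasing, and a mid-peaking profile sized to the design.
#' @param genes_per_profile Genes planted on each profile.
#' @param n_null Flat "null" genes carrying no temporal signal.
#' @param baseline_fpkm Median baseline FPKM; per-gene baselines are drawn
#'   lognormally around it.
#' @param noise_cv CV of multiplicative lognormal noise on FPKM.
#' @return Object of class `profile_plant`.
#' @export
profile_plant <- function(profiles = NULL, genes_per_profile = 300L,
                          n_null = 300L, baseline_fpkm = 50, noise_cv = 0.2) {
  if (!is.null(profiles)) {
    stopifnot(is.list(profiles), length(profiles) >= 1L)
    for (p in profiles) {
      if (p[1] != 0) stop("parameter error: profiles must start at 0", call. = FALSE)
    }
    if (is.null(names(profiles))) {
      names(profiles) <- paste0("shape", seq_along(profiles))
    }
  }
  if (genes_per_profile < 0L || n_null < 0L) {
    stop("parameter error: gene counts must be >= 0", call. = FALSE)
  }
  stopifnot(baseline_fpkm > 0, noise_cv >= 0)
  structure(list(profiles = profiles,
                 genes_per_profile = as.integer(genes_per_profile),
                 n_null = as.integer(n_null), baseline_fpkm = baseline_fpkm,
                 noise_cv = noise_cv),
            class = "profile_plant")
}

#' Simulate an FPKM matrix with genes planted on temporal profiles
#'
#' A gene planted on profile `v` has stage means
#' `baseline x 2^(v[t])` -- i.e. integer log2 fold changes versus the first
#' stage -- with multiplicative lognormal replicate noise; null genes are
#' flat.  The gene-to-profile truth table is returned alongside the matrix.
#'
#' @param plant A [profile_plant()].
#' @param design A [study_design()] supplying the expression sampling times
#'   (>= 2) and replicate count (>= 1 accepted here).
#' @param seed Integer RNG seed.
#' @return List with `matrix` (an [expression_matrix()]) and `truth` (data
#'   frame `gene`, `profile` -- a shape name or `"null"`).
#' @export
simulate_expression <- function(plant, design, seed) {
  stopifnot(inherits(plant, "profile_plant"), inherits(design, "study_design"))
  tp <- design$time_points
  if (length(tp) < 2L) stop("parameter error: need >= 2 time points", call. = FALSE)
  nrep <- design$replicates
  profiles <- plant$profiles
  if (is.null(profiles)) profiles <- default_profiles(length(tp))
  for (p in profiles) {
    if (length(p) != length(tp)) {
      stop("parameter error: profile length must equal the number of time points",
           call. = FALSE)
    }
  }
  n_genes <- plant$genes_per_profile * length(profiles) + plant$n_null
  if (n_genes < 1L) stop("parameter error: zero genes requested", call. = FALSE)
  set.seed(seed)
  shapes <- c(rep(names(profiles), each = plant$genes_per_profile),
              rep("null", plant$n_null))
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  baselines <- stats::rlnorm(n_genes, meanlog = log(plant$baseline_fpkm), sdlog = 0.5)
  mat <- matrix(0, nrow = n_genes, ncol = length(tp) * nrep,
                dimnames = list(genes, paste0(rep(tp, each = nrep), "DAF_r",
                                              rep(seq_len(nrep), length(tp)))))
  for (g in seq_len(n_genes)) {
    v <- if (shapes[g] == "null") numeric(length(tp)) else profiles[[shapes[g]]]
    mu <- baselines[g] * 2^v
    mat[g, ] <- rep(mu, each = nrep) * lognormal_noise(length(tp) * nrep,
                                                       plant$noise_cv)
  }
  list(matrix = expression_matrix(mat),
       truth = data.frame(gene = genes, profile = shapes, stringsAsFactors = FALSE))
}

#' Draw a random panel of element archetypes
#'
#' Used for recovery experiments: `n_early` inflections are placed at or
#' before the first sampling time, `n_mid` between 9 and 21 DAF (the band in
#' which grain filling peaks), `n_sustained` at or beyond the last sampling
#' time.  Asymptotes and rates are drawn uniformly from realistic ranges
#' (`a` in [5, 50] content units, `k` in [0.15, 0.5] per day).
#'
#' @param n_early,n_mid,n_sustained Number of archetypes per class.
#' @param design A [study_design()].
#' @param seed Integer RNG seed.
#' @param noise_cv Replicate noise CV shared by all archetypes.
#' @return Named list of [element_archetype()] (names `E001`, `E002`, ...),
#'   with the planted class recoverable from each archetype's `label`.
#' @export
archetype_panel <- function(n_early, n_mid, n_sustained, design, seed,
                            noise_cv = 0.1) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  t1 <- design$time_points[1]
  tL <- design$time_points[length(design$time_points)]
  n <- n_early + n_mid + n_sustained
  labels <- rep(c("early", "mid", "sustained"), c(n_early, n_mid, n_sustained))
  xc <- c(stats::runif(n_early, t1 - 4, t1),
          stats::runif(n_mid, 9, 21),
          stats::runif(n_sustained, tL, tL + 10))
  a <- stats::runif(n, 5, 50)
  k <- stats::runif(n, 0.15, 0.5)
  out <- lapply(seq_len(n), function(i) {
    element_archetype(labels[i], a = a[i], k = k[i], x_c = xc[i],
                      noise_cv = noise_cv)
  })
  names(out) <- sprintf("E%03d", seq_len(n))
  out
}
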