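# Pipeline plumbing: run configuration, the synthetic study bundle, and the
# staged fit -> classify -> budget -> trend run with per-stage outputs and a
# machine-readable summary.  All randomness flows from the config seed; a
# fixed seed and fixed inputs reproduce byte-identical numeric outputs (the
# run log with wall-clock timings is kept separate).

#' Run configuration for the analysis pipeline
#'
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Output directory (created if needed).
#' @param drymatter_element Element label holding the dry-matter series used
#'   as the mid-pattern timing reference.
#' @param budget_window DAF endpoints for the redistribution budget; `NULL`
#'   uses the first and last design times.
#' @param log2_threshold Trend filter on `max |log2 ratio|`.
#' @param eps Pseudo-FPKM in the log2-ratio transform.
#' @param profile_c Maximum unit change per step of candidate profiles.
#' @param n_profiles Number of model profiles to select.
#' @param alpha Significance level for profile significance (Bonferroni
#'   corrected over the profile count).
#' @param fit Fit options from [fit_options()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("grainfill_run_"),
                       drymatter_element = "dry_matter", budget_window = NULL,
                       log2_threshold = 1, eps = 1, profile_c = 2L,
                       n_profiles = 20L, alpha = 0.05, fit = fit_options()) {
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), log2_threshold >= 0, eps >= 0, profile_c >= 1,
            n_profiles >= 1, alpha > 0, alpha < 1)
  structure(list(seed = seed, out_dir = out_dir,
                 drymatter_element = drymatter_element,
                 budget_window = budget_window,
                 log2_threshold = log2_threshold, eps = eps,
                 profile_c = as.integer(profile_c),
                 n_profiles = as.integer(n_profiles), alpha = alpha, fit = fit),
            class = "run_config")
}

#' The built-in 14-element study panel
#'
#' Archetype parameters for grain dry matter and 14 elements, chosen so each
#' element's timing class (4 early, 9 mid, 1 sustained) and closed-form peak
#' accumulation rate `a k / 4` match the values a grain-filling field study
#' of a japonica rice cultivar reports: dry matter peaks at 1.35 mg/d at
#' 13 DAF; N, P, Mg, S peak near dry matter at 12.1, 3.9, 1.6, 1.8 ug/d;
#' Cu, Zn, Mo at 5.1, 33.3, 0.3 ng/d; As, Cd at 116.3, 7.6 pg/d; Fe sustains
#' accumulation to a 13.8 ng/d peak at 30 DAF.  The flag-leaf and node-I
#' contribution fractions reproduce reported budget magnitudes (flag-leaf K
#' 18.5%, node-I Cd 26.8%); the flag leaf is a sink (negative fraction) for
#' Ca and Mn.
#'
#' @return Data frame: `element`, `label`, `a`, `k`, `x_c`, `unit`,
#'   `source_fraction`, `node_fraction`.
#' @export
study_panel <- function() {
  p <- utils::read.csv(text = "
element,label,k,x_c,peak,unit,source_fraction,node_fraction
dry_matter,mid,0.25,13,1.35,mg,0,0
K,early,0.35,4,18,ug,0.185,0.05
Ca,early,0.40,3,6,ug,-0.10,0.02
Mn,early,0.30,4,20,ng,-0.08,0.03
B,early,0.30,4,12,ng,0.06,0.01
N,mid,0.25,13,12.1,ug,0.12,0.04
P,mid,0.25,13,3.9,ug,0.10,0.03
Mg,mid,0.25,13,1.6,ug,0.08,0.02
S,mid,0.28,12,1.8,ug,0.07,0.05
Cu,mid,0.28,12,5.1,ng,0.05,0.08
Zn,mid,0.28,12,33.3,ng,0.09,0.06
Mo,mid,0.24,14,0.3,ng,0.04,0.01
As,mid,0.28,12,116.3,pg,0.30,0.08
Cd,mid,0.25,14,7.6,pg,0.05,0.268
Fe,sustained,0.15,32,13.8,ng,0.06,0.02
", stringsAsFactors = FALSE, strip.white = TRUE)
  p$a <- 4 * p$peak / p$k
  p[c("element", "label", "a", "k", "x_c", "unit",
      "source_fraction", "node_fraction")]
}

#' Simulate a complete synthetic study bundle on disk
#'
#' Writes the input files the pipeline consumes: a tidy content table with
#' grain, flag-leaf, and node-I series for the [study_panel()] elements
#' (7 DAF x 4 replicates), an FPKM matrix with genes planted on decreasing,
#' mid-peaking, and increasing profiles over 5 stages x 3 replicates, and
#' ground-truth sidecar tables.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param seed Integer seed.
#' @param noise_cv Replicate noise CV for element contents.
#' @param genes_per_profile,n_null Expression generator sizes.
#' @param expression_noise_cv FPKM noise CV.
#' @return Invisible list of the written paths (`content`, `expression`,
#'   `truth_elements`, `truth_genes`) plus the designs used.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, noise_cv = 0.05,
                            genes_per_profile = 300L, n_null = 200L,
                            expression_noise_cv = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- study_panel()
  design <- study_design(elements = panel$element,
                         units = stats::setNames(panel$unit, panel$element))
  series <- list()
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    arch <- element_archetype(row$label, a = row$a, k = row$k, x_c = row$x_c,
                              noise_cv = noise_cv)
    if (row$element == "dry_matter") {
      s <- simulate_grain_series(arch, design, seed = seed + i,
                                 element = row$element, unit = row$unit)
      series[[length(series) + 1L]] <- s
    } else {
      trio <- simulate_tissue_budget(row$element, row$source_fraction,
                                     row$node_fraction, design,
                                     seed = seed + i, archetype = arch,
                                     noise_cv = noise_cv, unit = row$unit)
      series <- c(series, trio)
    }
  }
  content_path <- file.path(out_dir, "content.csv")
  write_content_table(series, content_path)

  expr_design <- study_design(time_points = c(5L, 9L, 13L, 17L, 21L),
                              replicates = 3L)
  plant <- profile_plant(genes_per_profile = genes_per_profile, n_null = n_null,
                         noise_cv = expression_noise_cv)
  sim <- simulate_expression(plant, expr_design, seed = seed + 1000L)
  expression_path <- file.path(out_dir, "expression.tsv")
  write_expression_matrix(sim$matrix, expression_path)

  truth_el <- file.path(out_dir, "truth_elements.csv")
  utils::write.csv(panel, truth_el, row.names = FALSE, quote = FALSE)
  truth_genes <- file.path(out_dir, "truth_genes.tsv")
  utils::write.table(sim$truth, truth_genes, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(content = content_path, expression = expression_path,
                 truth_elements = truth_el, truth_genes = truth_genes,
                 design = design, expression_design = expr_design))
}

write_num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in order: fit (logistic fits of all grain series), classify
#' (pattern labels against the dry-matter fit, empirical fallback when a fit
#' fails), budget (redistribution budget per element with vegetative
#' series), trend (log2-ratio filter, profile selection, gene assignment,
#' exact permutation significance, PCA).  Each stage writes a result table
#' under `config$out_dir`; a failed stage aborts the stages downstream of it
#' and is recorded with its cause.  The trend stage is skipped (and logged
#' as skipped) when no expression input is given.
#'
#' @param config A [run_config()].
#' @param content_path Tidy content table (CSV/TSV); required.
#' @param expression_path FPKM matrix TSV, or `NULL` to skip the trend stage.
#' @param design A [study_design()]; inferred from the content table when
#'   `NULL`.
#' @return Invisible list with per-stage results, stage status, and the
#'   paths written (also serialized to `summary.json`).
#' @export
run_pipeline <- function(config, content_path, expression_path = NULL,
                         design = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_lines <- character()
  t0 <- proc.time()[["elapsed"]]
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%7.2fs] %s",
                                       proc.time()[["elapsed"]] - t0,
                                       paste0(...)))
  }
  status <- list()
  results <- list()
  aborted <- FALSE

  run_stage <- function(name, fun) {
    if (aborted) {
      status[[name]] <<- "aborted: upstream failure"
      note("stage ", name, " aborted (upstream failure)")
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(out))
      note("stage ", name, " FAILED: ", conditionMessage(out))
      aborted <<- TRUE
      NULL
    } else {
      status[[name]] <<- "ok"
      note("stage ", name, " ok")
      out
    }
  }

  # -- load ------------------------------------------------------------
  loaded <- run_stage("load", function() {
    if (is.null(design)) {
      tab <- read_delim_auto(content_path)
      if (!all(c("element", "daf", "replicate", "unit") %in% names(tab))) {
        stop("schema error: content table lacks required columns", call. = FALSE)
      }
      els <- unique(tab$element)
      units <- vapply(els, function(e)
        normalize_unit(tab$unit[tab$element == e][1]), character(1))
      design <- study_design(time_points = sort(unique(tab$daf)),
                             replicates = max(2L, max(tab$replicate)),
                             tissues = unique(tab$tissue), elements = els,
                             units = units)
    }
    series <- read_content_table(content_path, design)
    note("loaded ", length(series), " series from ", content_path)
    list(series = series, design = design)
  })

  window <- NULL
  fits <- NULL
  if (!is.null(loaded)) {
    tp <- loaded$design$time_points
    window <- c(tp[1], tp[length(tp)])
  }

  # -- fit -------------------------------------------------------------
  fits <- run_stage("fit", function() {
    grain <- Filter(function(s) s$tissue == "grain", loaded$series)
    fl <- lapply(grain, fit_logistic, options = config$fit)
    tab <- do.call(rbind, lapply(fl, function(f) {
      se <- sqrt(pmax(diag(f$vcov), 0))
      data.frame(element = f$element, a = f$a, k = f$k, x_c = f$x_c,
                 se_a = se[1], se_k = se[2], se_x_c = se[3],
                 r_squared = f$r_squared,
                 t_peak = if (f$converged) f$x_c else NA_real_,
                 peak_rate = if (f$converged) f$a * f$k / 4 else NA_real_,
                 unit = f$unit, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    write_num_csv(tab, file.path(config$out_dir, "fits.csv"))
    note("fitted ", nrow(tab), " grain series (",
         sum(tab$converged), " converged)")
    list(fits = fl, table = tab)
  })

  # -- classify --------------------------------------------------------
  patterns <- run_stage("classify", function() {
    dm_key <- paste(config$drymatter_element, "grain", sep = ":")
    dm_fit <- fits$fits[[dm_key]]
    if (is.null(dm_fit)) {
      stop("contract error: dry-matter series '", config$drymatter_element,
           "' not found", call. = FALSE)
    }
    check_converged(dm_fit)
    keys <- setdiff(names(fits$fits), dm_key)
    labels <- do.call(rbind, lapply(keys, function(kk) {
      classify_element(loaded$series[[kk]], fits$fits[[kk]], dm_fit, window)
    }))
    write_num_csv(labels, file.path(config$out_dir, "patterns.csv"))
    summary_tab <- summarize_patterns(labels)
    write_num_csv(summary_tab, file.path(config$out_dir, "pattern_summary.csv"))
    note("classified ", nrow(labels), " elements into ",
         sum(summary_tab$n > 0), " pattern classes")
    list(labels = labels, summary = summary_tab)
  })

  # -- budget ----------------------------------------------------------
  budget <- run_stage("budget", function() {
    bw <- config$budget_window
    if (is.null(bw)) bw <- window
    tissues_of <- split(loaded$series,
                        vapply(loaded$series, function(s) s$element, character(1)))
    rows <- list()
    for (el in names(tissues_of)) {
      grp <- tissues_of[[el]]
      tns <- vapply(grp, function(s) s$tissue, character(1))
      if (!all(c("grain", "flag_leaf", "node_I") %in% tns)) next
      rows[[el]] <- assemble_budget(grp, window = bw)
    }
    if (!length(rows)) {
      note("budget skipped: no element with grain, flag_leaf and node_I series")
      return(list(table = NULL))
    }
    tab <- do.call(rbind, rows[order(names(rows))])
    rownames(tab) <- NULL
    write_num_csv(tab, file.path(config$out_dir, "budget.csv"))
    note("budget assembled for ", length(rows), " elements")
    list(table = tab)
  })

  # -- trend -----------------------------------------------------------
  trend <- if (is.null(expression_path)) {
    status[["trend"]] <- "skipped: no expression input"
    note("stage trend skipped (no expression input)")
    NULL
  } else {
    run_stage("trend", function() {
      em <- read_expression_matrix(expression_path)
      filt <- log2_ratio_filter(em, threshold = config$log2_threshold,
                                eps = config$eps)
      n_time <- ncol(filt$ratios)
      cands <- generate_candidate_profiles(n_time, config$profile_c)
      profiles <- select_model_profiles(cands, config$n_profiles)
      asg <- assign_genes(filt$ratios_kept, profiles)
      sig <- profile_significance(asg, filt$ratios_kept,
                                  mode = if (n_time <= 7) "exact" else "sampled",
                                  alpha = config$alpha, seed = config$seed)
      pca <- pca_samples(em)
      utils::write.table(asg$assignments,
                         file.path(config$out_dir, "assignments.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(sig, file.path(config$out_dir, "profiles.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      pca_tab <- data.frame(sample = rownames(pca$scores),
                            round(pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                             drop = FALSE], 10))
      write_num_csv(pca_tab, file.path(config$out_dir, "pca_scores.csv"))
      note("trend: ", length(filt$kept), "/", nrow(filt$ratios),
           " genes kept; ", sum(sig$significant), " significant profiles")
      list(filter = filt, profiles = profiles, assignment = asg,
           significance = sig, pca = pca)
    })
  }

  # -- summary ---------------------------------------------------------
  summary_obj <- list(
    seed = config$seed,
    stages = status,
    n_series = if (is.null(loaded)) 0L else length(loaded$series),
    n_fits_converged = if (is.null(fits)) NA else sum(fits$table$converged),
    pattern_counts = if (is.null(patterns)) NULL else
      stats::setNames(as.list(patterns$summary$n), patterns$summary$pattern),
    n_budget_elements = if (is.null(budget) || is.null(budget$table)) 0L else
      length(unique(budget$table$element)),
    n_genes_kept = if (is.null(trend)) NULL else length(trend$filter$kept),
    n_significant_profiles = if (is.null(trend)) NULL else
      sum(trend$significance$significant),
    pc1_percent = if (is.null(trend)) NULL else
      round(100 * trend$pca$var_explained[1], 6)
  )
  jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  config_ser <- config
  config_ser$fit <- unclass(config_ser$fit)
  config_ser$out_dir <- NULL   # path is implicit; keeps outputs relocatable
  jsonlite::write_json(unclass(config_ser),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(list(series = if (is.null(loaded)) NULL else loaded$series,
                 design = if (is.null(loaded)) NULL else loaded$design,
                 fits = fits, patterns = patterns, budget = budget,
                 trend = trend, status = status, summary = summary_obj,
                 out_dir = config$out_dir))
}
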