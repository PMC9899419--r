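# Short time-series profile mining in the STEM style: candidate integer
# profiles with bounded unit changes, greedy max-min selection under
# correlation distance, gene assignment by maximum Pearson correlation of
# log2-ratio trajectories, and exact time-order permutation significance.

#' FPKM normalization of a count matrix
#'
#' `FPKM = count x 1e9 / (gene length x library size)`.
#'
#' @param counts Non-negative gene x sample matrix with sample columns named
#'   `<daf>DAF_r<rep>` and gene rownames.
#' @param lengths Gene lengths in bp (> 0), in row order or named by gene.
#' @param lib_sizes Mapped fragments per sample (> 0), in column order or
#'   named by sample.
#' @return An [expression_matrix()] of FPKM values.
#' @export
fpkm_normalize <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(lib_sizes))) lib_sizes <- lib_sizes[colnames(counts)]
  if (any(lengths <= 0) || anyNA(lengths)) {
    stop("domain error: gene lengths must be > 0", call. = FALSE)
  }
  if (any(lib_sizes <= 0) || anyNA(lib_sizes)) {
    stop("domain error: library sizes must be > 0", call. = FALSE)
  }
  fpkm <- sweep(counts / lengths, 2, lib_sizes, "/") * 1e9
  expression_matrix(fpkm)
}

#' Replicate-mean FPKM matrix by developmental stage
#'
#' @param em An [expression_matrix()].
#' @return Gene x stage matrix of replicate means, columns ordered by DAF
#'   and named by DAF.
#' @export
stage_means <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  stages <- sort(unique(em$samples$daf))
  out <- vapply(stages, function(t) {
    rowMeans(em$fpkm[, em$samples$daf == t, drop = FALSE])
  }, numeric(nrow(em$fpkm)))
  out <- matrix(out, nrow = nrow(em$fpkm),
                dimnames = list(rownames(em$fpkm), as.character(stages)))
  out
}

#' Log2 expression ratios versus the first developmental stage
#'
#' `e_gt = log2((M_gt + eps) / (M_g1 + eps))` on replicate-mean FPKM, with a
#' pseudo-value `eps` guarding silent genes.  The first column is identically
#' zero by construction.
#'
#' @param em An [expression_matrix()].
#' @param eps Pseudo-FPKM added before the ratio (default 1).
#' @return Gene x stage matrix of log2 ratios.
#' @export
log2_ratio <- function(em, eps = 1) {
  m <- stage_means(em)
  log2((m + eps) / (m[, 1] + eps))
}

#' Filter genes by maximum absolute log2 ratio
#'
#' A gene is retained iff `max_t |e_gt| >= threshold` (boundary inclusive),
#' the standard "log2ratio >= 1" trend-analysis filter at the default.
#'
#' @param em An [expression_matrix()].
#' @param threshold Minimum absolute log2 ratio (default 1).
#' @param eps Pseudo-FPKM for the ratio transform.
#' @return List with `ratios` (all genes), `kept` (gene ids passing the
#'   filter), and `ratios_kept` (filtered ratio matrix).
#' @export
log2_ratio_filter <- function(em, threshold = 1, eps = 1) {
  e <- log2_ratio(em, eps = eps)
  keep <- apply(abs(e), 1, max) >= threshold
  list(ratios = e, kept = rownames(e)[keep],
       ratios_kept = e[keep, , drop = FALSE])
}

#' Enumerate candidate model profiles
#'
#' All integer-valued temporal templates of length `n_time` that start at 0
#' and change by at most `c` units between consecutive stages, excluding the
#' all-zero profile: `(2c+1)^(n_time-1) - 1` candidates, in lexicographic
#' order of their value vectors.
#'
#' @param n_time Number of stages, >= 2.
#' @param c Maximum unit change per step, >= 1.
#' @return Integer matrix, one candidate per row.
#' @export
generate_candidate_profiles <- function(n_time, c = 2L) {
  stopifnot(n_time >= 2, c >= 1)
  steps <- seq.int(-c, c)
  diffs <- as.matrix(expand.grid(rep(list(steps), n_time - 1L)))
  cum <- diffs
  if (ncol(diffs) > 1L) {
    for (j in 2:ncol(diffs)) cum[, j] <- cum[, j - 1L] + diffs[, j]
  }
  vals <- cbind(0L, cum)
  vals <- vals[rowSums(vals != 0) > 0, , drop = FALSE]
  vals <- vals[do.call(order, as.data.frame(vals)), , drop = FALSE]
  dimnames(vals) <- NULL
  storage.mode(vals) <- "integer"
  vals
}

profile_cor_dist <- function(profiles) {
  1 - stats::cor(t(profiles))
}

#' Select a diverse set of model profiles by greedy max-min
#'
#' Distance between profiles is `1 - Pearson correlation` of their value
#' vectors.  Selection seeds with the two most distant candidates and then
#' repeatedly adds the candidate maximizing its minimum distance to the
#' selected set; ties break to the lexicographically smallest candidate.
#' Selected profiles get ids `0..m-1` in ascending lexicographic order.
#'
#' @param candidates Candidate matrix from [generate_candidate_profiles()]
#'   (assumed lexicographically ordered, as generated).
#' @param m Number of profiles to select, <= number of candidates.
#' @return Integer matrix of `m` selected profiles, rownames `"0".."m-1"`.
#' @export
select_model_profiles <- function(candidates, m) {
  n <- nrow(candidates)
  if (m > n) stop("parameter error: m exceeds candidate count", call. = FALSE)
  if (m == n) {
    sel <- seq_len(n)
  } else {
    d <- profile_cor_dist(candidates)
    # seed: the lexicographically first pair attaining the maximum distance
    dmax <- max(d)
    hit <- which(d >= dmax - 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    sel <- as.integer(hit[1, ])
    while (length(sel) < m) {
      rest <- setdiff(seq_len(n), sel)
      mind <- apply(d[rest, sel, drop = FALSE], 1, min)
      sel <- c(sel, rest[which.max(mind)])  # which.max takes the first = lex order
    }
  }
  sel <- sort(sel)
  out <- candidates[sel, , drop = FALSE]
  rownames(out) <- as.character(seq_len(length(sel)) - 1L)
  out
}

# Max-correlation assignment of ratio rows to profile rows; zero-variance
# rows are unassignable (NA).  Ties take the lowest profile id.
assign_core <- function(ratios, profiles) {
  sds <- apply(ratios, 1, stats::sd)
  ok <- sds > 0
  best <- rep(NA_integer_, nrow(ratios))
  bestcor <- rep(NA_real_, nrow(ratios))
  if (any(ok)) {
    cc <- stats::cor(t(ratios[ok, , drop = FALSE]), t(profiles))
    idx <- max.col(cc, ties.method = "first")
    best[ok] <- idx
    bestcor[ok] <- cc[cbind(seq_len(sum(ok)), idx)]
  }
  list(best = best, cor = bestcor, ok = ok)
}

#' Assign genes to their best-matching model profile
#'
#' Each gene's log2-ratio trajectory is assigned to the selected profile with
#' the largest Pearson correlation (distance reported as `1 - r`); ties go to
#' the lowest profile id.  Constant trajectories (zero variance) cannot be
#' correlated and are excluded, with the count recorded.
#'
#' @param ratios Gene x stage log2-ratio matrix (filtered genes).
#' @param profiles Selected profile matrix from [select_model_profiles()].
#' @return Object of class `profile_assignment`: data frame `assignments`
#'   (`gene`, `profile`, `distance`), the profile matrix, and `n_excluded`.
#' @export
assign_genes <- function(ratios, profiles) {
  if (is.null(dim(ratios)) || nrow(ratios) == 0L) {
    stop("input error: empty gene set", call. = FALSE)
  }
  a <- assign_core(ratios, profiles)
  ids <- as.integer(rownames(profiles))
  asg <- data.frame(gene = rownames(ratios)[a$ok],
                    profile = ids[a$best[a$ok]],
                    distance = 1 - a$cor[a$ok],
                    stringsAsFactors = FALSE)
  structure(list(assignments = asg, profiles = profiles,
                 n_excluded = sum(!a$ok)),
            class = "profile_assignment")
}

#' @export
print.profile_assignment <- function(x, ...) {
  cat(sprintf("<profile_assignment> %d genes over %d profiles (%d zero-variance excluded)\n",
              nrow(x$assignments), nrow(x$profiles), x$n_excluded))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

profile_shape_string <- function(profiles) {
  apply(profiles, 1, paste, collapse = ",")
}

#' Permutation significance of profile sizes
#'
#' The expected size of each profile is the mean number of genes assigned to
#' it when the time order of every trajectory is permuted -- exhaustively
#' over all `T!` orders (`exact` mode, the default for <= 7 stages) or over
#' `n_perm` sampled orders.  Because the ratios are log differences, a
#' permuted trajectory is re-referenced by subtracting its new first value,
#' exactly reproducing ratios computed from permuted stage means.  The
#' p-value is the binomial tail `P(X >= observed)` with `n` assigned genes
#' and success probability `expected / n`; profiles are flagged significant
#' at `alpha` after Bonferroni correction over the profile count.
#'
#' @param assignment A [assign_genes()] result on the observed ratios.
#' @param ratios The gene x stage log2-ratio matrix the assignment used.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_perm Number of sampled permutations (sampled mode).
#' @param alpha Significance level before Bonferroni correction.
#' @param seed RNG seed for sampled mode.
#' @return Data frame per profile: `profile`, `shape`, `size`, `expected`,
#'   `p_value`, `significant`.
#' @export
profile_significance <- function(assignment, ratios, mode = c("exact", "sampled"),
                                 n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(assignment, "profile_assignment"))
  mode <- match.arg(mode)
  profiles <- assignment$profiles
  n_time <- ncol(ratios)
  if (mode == "exact" && n_time > 7L) {
    stop("parameter error: exact mode enumerates T! orders and is limited to ",
         "T <= 7; use mode = 'sampled'", call. = FALSE)
  }
  perms <- if (mode == "exact") {
    all_permutations(n_time)
  } else {
    set.seed(seed)
    t(replicate(n_perm, sample.int(n_time)))
  }
  m <- nrow(profiles)
  counts <- matrix(0, nrow(perms), m)
  for (i in seq_len(nrow(perms))) {
    rp <- ratios[, perms[i, ], drop = FALSE]
    rp <- rp - rp[, 1]
    a <- assign_core(rp, profiles)
    counts[i, ] <- tabulate(a$best[a$ok], nbins = m)
  }
  expected <- colMeans(counts)
  ids <- as.integer(rownames(profiles))
  observed <- tabulate(match(assignment$assignments$profile, ids), nbins = m)
  n_assigned <- sum(observed)
  p <- stats::pbinom(observed - 1, n_assigned,
                     pmin(expected / n_assigned, 1), lower.tail = FALSE)
  data.frame(profile = ids, shape = profile_shape_string(profiles),
             size = observed, expected = expected, p_value = p,
             significant = p < alpha / m, stringsAsFactors = FALSE)
}

#' Principal component analysis of samples
#'
#' PCA on gene-centered `log2(FPKM + 1)`, samples as observations.
#'
#' @param em An [expression_matrix()] with >= 2 samples.
#' @return List with `scores` (sample x PC matrix), `var_explained`
#'   (non-increasing fractions summing to <= 1), and the sample metadata.
#' @export
pca_samples <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$fpkm) < 2L) {
    stop("input error: need >= 2 samples for PCA", call. = FALSE)
  }
  x <- t(log2(em$fpkm + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2),
       samples = em$samples)
}

zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  list(z = (mat - mu) / s, sd = s)
}

#' Hierarchical clustering of Z-scored rows
#'
#' Rows are Z-scored (when `scale = TRUE`), then clustered agglomeratively
#' with average linkage under Euclidean distance (default) or correlation
#' distance `1 - r`.  Zero-variance rows cannot be Z-scored and are dropped
#' with a warning.
#'
#' @param mat Numeric matrix with >= 2 rows (e.g. genes x stages).
#' @param distance `"euclidean"` or `"correlation"`.
#' @param scale Z-score rows first (default TRUE).
#' @return List with the `hclust` object, `labels` in leaf order, and
#'   `newick`, the dendrogram serialized as a Newick string.
#' @export
hierarchical_cluster <- function(mat, distance = c("euclidean", "correlation"),
                                 scale = TRUE) {
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  if (scale) {
    zs <- zscore_rows(mat)
    drop <- zs$sd == 0
    if (any(drop)) {
      warning(sum(drop), " zero-variance row(s) excluded from clustering",
              call. = FALSE)
    }
    mat <- zs$z[!drop, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("input error: need >= 2 usable rows", call. = FALSE)
  d <- if (distance == "euclidean") stats::dist(mat)
       else stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = hc$labels[hc$order], newick = newick)
}
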