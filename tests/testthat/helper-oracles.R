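# Independent oracles and shared fixtures for the test suite.  The oracles
# deliberately avoid the package's own code paths: the grid SSE oracle
# evaluates the logistic sum of squares by direct enumeration, and the
# assignment oracle recomputes Pearson correlations from first principles.

default_design <- function(replicates = 4L, ...) {
  study_design(replicates = replicates, ...)
}

expr_design <- function(replicates = 3L) {
  study_design(time_points = c(5L, 9L, 13L, 17L, 21L), replicates = replicates)
}

# Best SSE of W ~ a / (1 + exp(-k (x - x_c))) over an exhaustive grid
# spanning truth +/- span at n_grid points per parameter.
oracle_grid_sse <- function(x, W, truth, span = 0.5, n_grid = 101L) {
  gr <- function(v) seq(v * (1 - span), v * (1 + span), length.out = n_grid)
  as_ <- gr(truth[["a"]]); ks <- gr(truth[["k"]]); xcs <- gr(truth[["x_c"]])
  kx <- expand.grid(k = ks, x_c = xcs)
  P <- plogis(outer(kx$k, x) - kx$k * kx$x_c)       # (k,x_c) combos x obs
  sWE <- as.numeric(P %*% W)
  sEE <- rowSums(P^2)
  sWW <- sum(W^2)
  best <- Inf
  for (a in as_) {
    best <- min(best, min(sWW - 2 * a * sWE + a^2 * sEE))
  }
  best
}

# Brute-force max-correlation assignment: explicit Pearson formula, loops,
# first-index tie break.  Returns NA for zero-variance gene rows.
oracle_assign <- function(ratios, profiles) {
  pearson <- function(u, v) {
    un <- u - mean(u); vn <- v - mean(v)
    sum(un * vn) / sqrt(sum(un^2) * sum(vn^2))
  }
  out <- rep(NA_integer_, nrow(ratios))
  for (g in seq_len(nrow(ratios))) {
    u <- ratios[g, ]
    if (sd(u) == 0) next
    cors <- vapply(seq_len(nrow(profiles)), function(j)
      pearson(u, profiles[j, ]), numeric(1))
    out[g] <- which(cors >= max(cors) - 0)[1]
  }
  out
}

# Textbook Tukey studentized-range statistics for equal-sized groups:
# q = |mean_i - mean_j| / sqrt(MSE / n), p from ptukey.
oracle_tukey <- function(groups) {
  k <- length(groups)
  n <- unique(vapply(groups, length, integer(1)))
  stopifnot(length(n) == 1L)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (k * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  q <- abs(means[pairs[1, ]] - means[pairs[2, ]]) / sqrt(mse / n)
  p <- ptukey(q, nmeans = k, df = k * (n - 1), lower.tail = FALSE)
  data.frame(g1 = pairs[1, ], g2 = pairs[2, ], q = as.numeric(q),
             p = as.numeric(p), stringsAsFactors = FALSE)
}
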