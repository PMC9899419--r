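test_that("FPKM normalization matches its defining formula", {
  counts <- matrix(c(100, 0, 50, 200), 2, 2,
                   dimnames = list(c("g1", "g2"), c("5DAF_r1", "9DAF_r1")))
  em <- fpkm_normalize(counts, lengths = c(1000, 2000), lib_sizes = c(1e7, 1e7))
  expect_identical(unname(em$fpkm["g1", "5DAF_r1"]), 10)   # 100*1e9/(1000*1e7)
  expect_identical(unname(em$fpkm["g2", "5DAF_r1"]), 0)
  # doubling counts and library sizes leaves FPKM unchanged
  em2 <- fpkm_normalize(2 * counts, c(1000, 2000), 2 * c(1e7, 1e7))
  expect_equal(em2$fpkm, em$fpkm, tolerance = 1e-12)
  expect_error(fpkm_normalize(counts, c(1000, 2000), c(0, 1e7)), "domain error")
  expect_error(fpkm_normalize(counts, c(0, 2000), c(1e7, 1e7)), "domain error")
})

test_that("log2 ratios are zero at the first stage and filter is boundary-inclusive", {
  sim <- simulate_expression(profile_plant(genes_per_profile = 30, n_null = 30,
                                           noise_cv = 0.2),
                             expr_design(), seed = 8)
  e <- log2_ratio(sim$matrix)
  expect_true(all(e[, 1] == 0))
  # a gene exactly doubling from stage 1 to 2 sits on the threshold and is kept
  m <- matrix(c(10, 10, 20, 20, 10, 10, 10, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("dbl", "flat"),
                              c("5DAF_r1", "5DAF_r2", "9DAF_r1", "9DAF_r2")))
  filt <- log2_ratio_filter(expression_matrix(m), threshold = 1, eps = 0)
  expect_identical(filt$kept, "dbl")
  # filter is monotone in the threshold
  sizes <- vapply(c(0.5, 1, 1.5, 2), function(th)
    length(log2_ratio_filter(sim$matrix, threshold = th)$kept), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("candidate profile enumeration matches the closed-form count", {
  expect_identical(nrow(generate_candidate_profiles(3, 1)), 8L)    # 3^2 - 1
  expect_identical(nrow(generate_candidate_profiles(5, 1)), 80L)   # 3^4 - 1
  expect_identical(nrow(generate_candidate_profiles(5, 2)), 624L)  # 5^4 - 1
  p2 <- generate_candidate_profiles(2, 1)
  expect_identical(nrow(p2), 2L)
  expect_true(all(p2[, 1] == 0))
  cands <- generate_candidate_profiles(5, 2)
  expect_true(all(cands[, 1] == 0))
  expect_true(all(abs(cands[, -1] - cands[, -5]) <= 2))
  expect_false(any(rowSums(cands != 0) == 0))      # all-zero excluded
  expect_identical(anyDuplicated(cands), 0L)
})

test_that("greedy selection seeds with a maximally anticorrelated pair", {
  cands <- generate_candidate_profiles(3, 1)
  sel <- select_model_profiles(cands, 2)
  # brute force over all pairs: max distance is 2 (r = -1)
  d <- 1 - cor(t(cands))
  expect_equal(max(d), 2, tolerance = 1e-12)
  dsel <- 1 - cor(sel[1, ], sel[2, ])
  expect_equal(dsel, 2, tolerance = 1e-12)
  # the lexicographically first such pair is strictly decreasing / increasing
  expect_identical(unname(sel[1, ]), c(0L, -1L, -2L))
  expect_identical(unname(sel[2, ]), c(0L, 1L, 2L))
  # m = candidate count returns everything
  expect_identical(nrow(select_model_profiles(cands, nrow(cands))), nrow(cands))
  expect_error(select_model_profiles(cands, nrow(cands) + 1), "parameter error")
})

test_that("greedy selection beats random subsets on min pairwise distance", {
  cands <- generate_candidate_profiles(5, 1)
  m <- 10
  sel <- select_model_profiles(cands, m)
  min_pair <- function(mat) min(as.dist(1 - cor(t(mat))))
  d_greedy <- min_pair(sel)
  set.seed(123)
  d_rand <- replicate(1000, min_pair(cands[sample(nrow(cands), m), ]))
  expect_true(all(d_greedy >= d_rand - 1e-12))
})

test_that("assignment equals the brute-force correlation oracle", {
  sim <- simulate_expression(profile_plant(genes_per_profile = 60, n_null = 40,
                                           noise_cv = 0.3),
                             expr_design(), seed = 13)
  filt <- log2_ratio_filter(sim$matrix, threshold = 0)
  profiles <- select_model_profiles(generate_candidate_profiles(5, 2), 20)
  ratios <- filt$ratios_kept[apply(filt$ratios_kept, 1, sd) > 0, , drop = FALSE]
  ratios <- ratios[seq_len(min(200, nrow(ratios))), , drop = FALSE]
  asg <- assign_genes(ratios, profiles)
  oracle <- oracle_assign(ratios, profiles)
  ids <- as.integer(rownames(profiles))
  expect_identical(asg$assignments$profile, ids[oracle[!is.na(oracle)]])
  # exact-match gene: distance 0 to its own profile
  exact <- matrix(as.numeric(profiles[3, ]), 1,
                  dimnames = list("exact", NULL))
  a1 <- assign_genes(exact, profiles)
  expect_identical(a1$assignments$profile, ids[3])
  expect_lt(a1$assignments$distance, 1e-12)
  # negating a monotone profile sends the gene to a perfectly anticorrelated
  # counterpart (the selected set contains a profile collinear with it)
  neg <- matrix(-as.numeric(profiles["0", ]), 1, dimnames = list("neg", NULL))
  a2 <- assign_genes(neg, profiles)
  expect_equal(cor(as.numeric(profiles[as.character(a2$assignments$profile), ]),
                   as.numeric(neg)), 1, tolerance = 1e-9)
  expect_error(assign_genes(ratios[0, , drop = FALSE], profiles), "input error")
})

test_that("zero-variance trajectories are excluded with a recorded count", {
  profiles <- select_model_profiles(generate_candidate_profiles(5, 1), 10)
  ratios <- rbind(sig = c(0, 1, 2, 1, 0), flat = c(0, 0, 0, 0, 0))
  asg <- assign_genes(ratios, profiles)
  expect_identical(nrow(asg$assignments), 1L)
  expect_identical(asg$n_excluded, 1L)
})

test_that("permutation significance detects planted signal and respects the mean", {
  profiles <- select_model_profiles(generate_candidate_profiles(5, 2), 20)
  # 300 genes planted exactly on a selected profile, noise off
  target <- profiles["0", ]
  ratios <- matrix(rep(as.numeric(target), each = 320), 320, 5)
  ratios[301:320, ] <- matrix(rnorm(100), 20, 5)  # background
  ratios[, 1] <- 0
  rownames(ratios) <- sprintf("g%03d", 1:320)
  asg <- assign_genes(ratios, profiles)
  sig <- profile_significance(asg, ratios, mode = "exact")
  expect_lt(sig$p_value[sig$profile == 0], 1e-6)
  expect_true(sig$significant[sig$profile == 0])
  # a profile at or below its permutation mean is never small-p (tail at mean)
  at_or_below <- sig$size <= floor(sig$expected)
  expect_true(any(at_or_below))
  expect_true(all(sig$p_value[at_or_below] >= 0.5))
  expect_error(profile_significance(asg, matrix(0, 2, 8), mode = "exact"),
               "sampled")
})

test_that("sampled-mode significance agrees with exact mode on direction", {
  sim <- simulate_expression(profile_plant(genes_per_profile = 50, n_null = 50),
                             expr_design(), seed = 31)
  filt <- log2_ratio_filter(sim$matrix, threshold = 1)
  profiles <- select_model_profiles(generate_candidate_profiles(5, 2), 20)
  asg <- assign_genes(filt$ratios_kept, profiles)
  ex <- profile_significance(asg, filt$ratios_kept, mode = "exact")
  sa <- profile_significance(asg, filt$ratios_kept, mode = "sampled",
                             n_perm = 200, seed = 5)
  expect_identical(ex$significant, sa$significant)
})

test_that("sample PCA has ordered variance fractions and exact 1-D structure", {
  # samples varying along exactly one direction -> PC1 explains 100%
  base <- runif(30, 1, 5)
  shift <- seq(0, 3, length.out = 4)
  fpkm <- 2^(outer(base, shift, "+")) - 1
  colnames(fpkm) <- c("5DAF_r1", "5DAF_r2", "9DAF_r1", "9DAF_r2")
  rownames(fpkm) <- paste0("g", 1:30)
  pc <- pca_samples(expression_matrix(fpkm))
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-9)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  sim <- simulate_expression(profile_plant(genes_per_profile = 40, n_null = 20),
                             expr_design(), seed = 17)
  pc2 <- pca_samples(sim$matrix)
  expect_true(all(diff(pc2$var_explained) <= 1e-12))
  one <- sim$matrix
  expect_error(pca_samples(expression_matrix(one$fpkm[, 1, drop = FALSE])),
               "input error")
})

test_that("hierarchical clustering is average-linkage with sane merges", {
  m <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3), c = c(3, 1, 0, 2))
  hc <- hierarchical_cluster(m, scale = FALSE)
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)  # identical rows first
  expect_true(all(diff(hc$hclust$height) >= -1e-12))       # monotone heights
  expect_match(hc$newick, "^\\(")
  # three points on a line: closest pair merges first
  line <- cbind(c(0, 1, 10))
  rownames(line) <- c("p0", "p1", "p10")
  hc2 <- hierarchical_cluster(line, scale = FALSE)
  expect_identical(sort(hc2$hclust$merge[1, ]), c(-2L, -1L))
  # zero-variance rows dropped with a warning under Z-scoring
  mz <- rbind(m, flat = c(2, 2, 2, 2), flat2 = c(5, 5, 5, 5))
  expect_warning(hc3 <- hierarchical_cluster(mz), "zero-variance")
  expect_identical(length(hc3$labels), 3L)
})
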