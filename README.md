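# grainfill

Kinetics of element accumulation, nutrient redistribution, and temporal
expression trends in developing cereal grain.

During grain filling (~5–30 days after fertilization, DAF) a rice grain
accumulates dry matter and mineral elements on element-specific schedules.
`grainfill` is for crop physiologists and ionomics/transcriptomics analysts
who have the standard field design — replicated per-grain contents across a
handful of DAF, flag-leaf and node contents at the window endpoints, and a
short RNA-seq time course — and want the full analysis as tested, seeded,
reproducible code.

The package provides:

* **Logistic kinetics** — fits `W(x) = a / (1 + exp(-k (x - x_c)))` to
  replicate-level content series (bounded Levenberg–Marquardt), and derives
  the accumulation-rate curve `W'(x) = a k p (1-p)` with its closed-form
  peak (`t_peak = x_c`, `peak = a k / 4`) and a delta-method *t* confidence
  band.
* **Pattern classification** — early / mid / sustained accumulation classes
  from the position of the fitted inflection relative to the sampling
  window, with a finite-difference Spearman fallback when a fit fails.
* **Redistribution budget** — net accumulation `ΔC_i = C_30,i − C_5,i` per
  tissue and contribution ratios `R_i = |ΔC_i| / C_30,grain × 100%` for
  source tissues, sinks reported by role, "other sources" as the remainder.
* **Expression trends** — FPKM normalization, log2 ratios versus the first
  stage, integer model profiles (all `(2c+1)^(T−1) − 1` candidates, greedy
  max–min selection of 20), maximum-correlation gene assignment, and exact
  120-permutation significance with Bonferroni control; plus sample PCA and
  average-linkage clustering of Z-scored trajectories.
* **Group statistics** — Z-scores, OLS regression with Pearson *r* and
  *t*-based confidence bands, one-way ANOVA with Tukey HSD and compact
  letter displays.
* **A synthetic-data generator** — logistic archetypes, source/sink tissue
  trios with planted contribution fractions, and planted-profile FPKM
  matrices, all with ground truth attached, so every stage is testable
  without field data.

## Worked example

Simulate a nitrogen-like mid-pattern series on the 7-stage design and fit
its kinetics:

```r
library(grainfill)

design <- study_design(elements = "N", units = c(N = "ug"))
arch   <- element_archetype("mid", a = 193.6, k = 0.25, x_c = 13, noise_cv = 0.05)
s      <- simulate_grain_series(arch, design, seed = 42, element = "N", unit = "ug")
fit    <- fit_logistic(s)
fit
#> <logistic_fit> N (grain)
#>   a = 190.4 ug, k = 0.2405 /d, x_c = 12.71 DAF (R2 = 0.9782, n = 28)
peak_rate(fit)
#> $t_peak
#> [1] 12.71417
#> $peak_rate
#> [1] 11.44567
```

The fitted inflection (12.7 DAF) and peak rate (11.4 µg d⁻¹) recover the
planted truth (13 DAF, `a k / 4` = 12.1 µg d⁻¹) from 28 noisy
observations; `confidence_band(fit, 5:30)` gives the pointwise 95% band.

A potassium-like budget with 18.5% of final grain content supplied by the
flag leaf and 5% by node I:

```r
b <- assemble_budget(simulate_tissue_budget("K", 0.185, 0.05, design,
                                            seed = 1, unit = "ug"))
print(b, digits = 4)
#>   element    tissue C_first C_last deltaC   role R_percent other_sources_percent
#> 1       K     grain   1.186  24.73 23.540   sink       0.0                  76.5
#> 2       K flag_leaf  16.937  12.36 -4.574 source      18.5                  76.5
#> 3       K    node_I  13.599  12.36 -1.236 source       5.0                  76.5
```

The planted fractions come back exactly and the budget conserves:
18.5 + 5 + 76.5 = 100.

The whole pipeline (fit → classify → budget → trend) runs from two input
files and one seed:

```r
b   <- simulate_bundle("study_in", seed = 7)          # 14 elements, 3 tissues, genes
res <- run_pipeline(run_config(seed = 7, out_dir = "study_out"),
                    b$content, b$expression)
res$patterns$summary
#>     pattern n                elements
#> 1     early 4               B,Ca,K,Mn
#> 2       mid 9 As,Cd,Cu,Mg,Mo,N,P,S,Zn
#> 3 sustained 1                      Fe
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/scripts/grainfill.R simulate --seed 7 --out study_in
Rscript inst/scripts/grainfill.R all --content study_in/content.csv \
    --expression study_in/expression.tsv --seed 7 --out study_out
```

Per-stage tables (`fits.csv`, `patterns.csv`, `budget.csv`,
`profiles.tsv`, `assignments.tsv`, `pca_scores.csv`) and a
machine-readable `summary.json` land in the output directory; equal seeds
reproduce them byte-identically.

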