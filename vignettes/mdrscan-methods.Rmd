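---
title: "Methods: pairwise variant-interaction scanning with cross-validated MDR"
author: "mdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise variant-interaction scanning with cross-validated MDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrscan)
```

# The problem and the model

Genome-wide association studies test variants one at a time; complex
diseases such as type 2 diabetes also involve joint (epistatic) effects of
variant pairs that single-variant tests cannot see. Testing all pairs
directly is both computationally heavy (n(n−1)/2 grows to ~10¹³ pairs for
cohort-scale variant counts, `countPairs(11297253)` ≈ 6×10¹³) and
statistically brutal under multiple-testing correction. `mdrscan`
implements the standard two-stage answer:

1. a cheap exhaustive **Pearson chi-square screen** over all pairs keeps
   only pairs showing some marginal-or-joint association signal
   (default p < 10⁻⁶), and
2. **Multifactor Dimensionality Reduction (MDR)** evaluates each
   surviving pair as a cross-validated contingency-table classifier and
   keeps only pairs whose predictive signal is stable across folds.

## The chi-square screen

For a pair (i, j), individuals with non-missing calls at both variants
are tallied into a 3×3 genotype-combination table split by case/control
status (a `PairTable`, 18 cells). The test treats the table as K×2, where
K is the number of genotype-combination columns with nonzero total:
columns that are empty in the data are dropped and df = K − 1. This is
the standard Pearson treatment of structurally empty categories and
avoids zero expected counts; the alternative (fixed df = 8) was examined
and is uniformly more conservative on the same tables, so nothing would
be gained by it. No continuity correction and no minimum expected-count
rule are applied — the screen is deliberately raw — but every result
carries an `expectedBelow5` flag and the scan reports how many retained
pairs had a fragile expected count.

The p-value is the upper-tail chi-square probability computed by
`stats::pchisq(lower.tail = FALSE)`, i.e. the regularized upper
incomplete gamma function, accurate to machine precision over the whole
range the screen uses.

**Small-sample behaviour.** With a few hundred individuals, the rare
genotype-combination cells (e.g. double homozygous-alternate) have
expected counts well below 1 and the chi-square approximation becomes
*conservative* in the tail: on null data the fraction of pairs passing a
nominal α = 0.01 falls below 0.01. In addition, p-values of pairs sharing
variants (and all sharing one phenotype) are correlated, so the retained
fraction of a single scan is noticeably over-dispersed relative to a
binomial count of independent tests. The calibration check in the test
suite measures exactly this quantity on a seeded 500-variant/400-individual
null cohort; its outcome should be read with both effects in mind. At the
default screening threshold of 10⁻⁶ conservatism only makes the screen
slightly stricter, which is the safe direction for a pre-filter.

## The MDR stage

For each fold of a stratified k-fold plan (step 1), each pair's training
table is built (step 2) and collapsed to one dimension (step 3): with
T = (training cases)/(training controls), a cell is **high risk** iff its
own case:control ratio strictly exceeds T. Held-out individuals are
classified case iff their genotype combination falls in a high-risk cell
(step 4), and prediction power is the held-out accuracy (precision is
computed alongside). After all folds, pairs are ranked per fold and the
top ⌈topFraction × nPairs⌉ form the fold's top set (step 5); a pair's
consistency is the number of folds whose top set contains it, and pairs
with consistency k are selected.

Decisions taken where the procedure is genuinely underdetermined:

* **Ranking metric.** "Prediction power" can be read as accuracy or as
  precision. The package ranks by held-out *accuracy* (the standard MDR
  criterion) and always reports precision alongside;
  `powerMetric = "precision"` switches the ranking, so both readings are
  reproducible.
* **Ties at the threshold.** A cell whose ratio equals T exactly is *low*
  risk (the rule is strictly greater). The comparison is implemented as
  integer cross-multiplication (cases_cell × controls_total >
  controls_cell × cases_total), so ties are decided exactly, never by
  floating-point luck.
* **Cells with no training controls** but some cases have unbounded ratio
  and are high risk. **Truly empty cells** get their own label and
  classify test individuals as *control*: an empty cell carries no
  evidence of risk, so the conservative call is the majority-protective
  one.
* **T is recomputed per training partition** (from the individuals behind
  the pair's training table, i.e. after missingness exclusion), not fixed
  from the full cohort.
* **Stratified CV.** Cases and controls are shuffled independently under
  the seed and dealt round-robin, so per-class fold sizes differ by at
  most one. An unstratified split can starve a fold of one class and make
  T undefined or unstable.
* **Ranking ties** are broken deterministically: higher mean
  training-table chi-square first, then lexicographic variant keys. This
  makes "top 20%" reproducible to the byte across pair orderings, chunk
  sizes and worker counts.
* **Degenerate folds** (no usable training cases/controls, or an empty
  usable test set) score NA, are excluded from mean power, and can never
  put the pair in that fold's top set — so a pair degenerate anywhere
  cannot reach consistency k.

## Vectorized counting

All tallies run through one-hot indicator matrices: H_a[ind, v] = 1 iff
individual *ind* carries code *a* at variant *v* (missing calls are zero
in all three indicators, which silently and correctly drops incomplete
individuals from every pair they cannot contribute to). Cell (a, b)
counts for a block of pairs sharing variant i are one vector–matrix
product H_a[, i]ᵀ H_b[, J] per status class. The per-individual loop
formulation exists only in the test suite, as the independent oracle the
matrix-product path must reproduce exactly — on random datasets with
missingness, every table, score, ranking and selection flag is required
to be identical.

# The synthetic cohort generator

`simulateDataset` emulates the structure of a genotyped case-control
cohort:

* **Null variants** are drawn under Hardy–Weinberg proportions
  (p², 2pq, q²) independently of phenotype, with MAFs uniform on
  (0.05, 0.5) by default — the common-variant range of a genotyping
  array; rare-variant panels are deliberately out of scope.
* **Planted pairs** follow a `PenetranceModel`: P(case | gA, gB) on the
  9 cells plus the two MAFs. Because the design is retrospective
  (case/control counts fixed by design, as in the cohorts this mimics),
  genotype pairs are sampled from the Bayes-inverted conditionals:
  P(g | case) ∝ P(case | g)·P(gA)·P(gB) and analogously for controls.
  The nominal prevalence therefore cancels; it is validated and echoed in
  the manifest only. `xorPenetrance()` (0.8/0.2 at MAF 0.4) is the
  canonical strong, purely epistatic test model — its effect size was
  fixed in advance by an independent pilot so that a 300/300 cohort
  recovers the pair at 5/5 consistency essentially always.
* The defaults (527/601-like splits, k = 5, top 20%) mirror the cohort
  scale the method is aimed at.

What the generator does **not** emulate: linkage disequilibrium between
variants, population stratification, genotyping error/missingness
patterns, covariates, and quantitative phenotypes. A green recovery test
therefore establishes that the pipeline detects a planted joint signal of
the stated size in an idealised cohort — not that it is robust to LD
leakage or confounding, which real analyses must address upstream.

# Numerical and operational choices

* Genotype codes survive CSV round-trips bit-exactly; an all-zero
  indicator triple is the only representable non-one-hot state in the
  one-hot layout and is defined as a missing call.
* `pThreshold` filtering is strict (p < t); a threshold of 1 means "no
  filtering" and also keeps pairs with p exactly 1 (zero statistic).
* Scan checkpoints are per-chunk TSVs written atomically (write + rename);
  file existence is the completion marker, safe under forked workers.
  Floats in checkpoints carry 17 significant digits so a resumed scan is
  byte-identical to an uninterrupted one; the user-facing TSV format
  rounds to 6 significant digits, deterministically.
* Seeded routines save and restore the caller's RNG state, so package
  calls never perturb a surrounding analysis.
* CLI configuration is JSON (not YAML), keeping the dependency footprint
  inside the supported stack; every command writes a JSON run manifest
  with config echo, input MD5 hashes, seed and per-stage counts.

# Limitations

* The chi-square screen's tail behaviour at small n is conservative (see
  above); at genome scale thresholds (10⁻⁶, Bonferroni ~10⁻⁸) this
  matters little but single-cohort calibration at loose α should not be
  over-read.
* Only pairwise interactions: higher-order models, permutation p-values
  for MDR scores, covariate adjustment, LD pruning and MAF filtering are
  out of scope.
* `countPairs` is exact up to n ≈ 1.3×10⁸ variants (result < 2⁵³);
  beyond that the double-precision value would round.
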