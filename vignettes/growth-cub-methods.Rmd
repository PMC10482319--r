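---
title: "Methods: growth-rate-dependent expression and codon usage bias"
author: "growthCUB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-rate-dependent expression and codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthCUB)
```

## The question and the model

Codon usage bias (CUB) in microbes is usually explained by translational
selection: genes that must be translated in bulk evolve codons matched to
the abundant tRNAs. But "expression level" is condition-dependent. This
package operationalizes a refinement: summarize each gene's relationship
to growth by the **Growth Correlation Index** — the Pearson correlation
between its log-scale expression and the population growth rate across
conditions — and ask whether GCI predicts CUB beyond mean expression.

The statistical objects are deliberately elementary (correlations, OLS,
t-tests, hypergeometric tails); the contribution is the pipeline that
composes them reproducibly: condition-aware preprocessing, CUB scoring,
the GCI with a permutation control, per-condition fit strength versus
growth rate, a four-model comparison, and functional-class analyses.

### CUB scores

A weight table assigns each sense codon a relative adaptiveness in
(0, 1]; a gene's score is the geometric mean of its codons' weights,
computed in log space (`exp(mean(log w))`) so thousand-codon genes do not
underflow. Choices a user should know about:

- **Stop codons** carry no weights in standard CAI/tAI tables, so the
  terminal stop is dropped by default (`dropStop = TRUE`); the start codon
  is retained (`dropStart = FALSE`). Both are flags because conventions
  vary and neither choice is forced by the score's definition.
- **Single-codon families** (ATG, TGG) get weight 1 in the illustrative
  tables, the classic convention; override via the weight table itself.
- **Ambiguous codons** (containing N) are excluded from both the product
  and the codon count rather than erroring — real annotations contain
  ambiguity and excluding them leaves the geometric mean of what was
  actually observed.
- **Weights of exactly 0** are rejected at load time: one such codon
  zeroes every gene that uses it. A user who wants that behavior must
  supply a small positive pseudo-weight explicitly.

The shipped table is deterministic and clearly labeled illustrative
(within-family weights `(i/k)^shape`); published weight tables should be
loaded with `loadWeightTable()` for real genomes.

CDS quality filters before scoring: length divisible by 3; declared
(coordinate) length equal to counted length where coordinates exist (for
plain FASTA this reduces to the divisibility check, since FASTA declares
no length); and length at most five times the median over **all** input
records, the median being computed before any removal so the filter is
order-independent.

### Expression preprocessing

The pipeline order is fixed and logged: normalize (if raw) → condition
filters → replicate averaging → duplicate exclusion → optional
sparse/neutral subsetting. Specifics:

- Raw abundances (protein copies per cell, fmol/mgDW) are transformed
  column-wise to `6 + log(a/Σa)` (natural log or log10 flavor). Zeros are
  replaced by the smallest nonzero value of the whole matrix **before**
  the transform, and the column total Σa is recomputed **after**
  replacement so the implied fractions still sum to one. (A per-column
  replacement variant is exposed as an option.)
- Condition filters drop columns with unknown or zero growth rate —
  zero may mean stationary phase or a reporting error, and GCI is
  meaningless without a growth measurement — and columns with alignment
  scores below 80 where scores exist.
- Replicate averaging is the arithmetic mean, on the stored log scale,
  of both expression and growth rate; strain flags merge by OR. Averaging
  after normalization matches how mixed-replicate compendia are processed.
- Duplicate expression profiles (all-by-all Spearman ρ = 1; average
  ranks for ties; a 1e-12 numerical guard because tied-rank correlations
  of long vectors round just below 1) are excluded **both-members** by
  default: identical profiles with different reported growth rates cannot
  be averaged or arbitrated. Constant columns have undefined rank
  correlations and are reported separately, never as duplicates.
- Sparse pruning iteratively removes one member (seeded uniform coin
  flip; lexicographically smallest pair on ties, for determinism) of the
  currently most-correlated condition pair until the target count
  remains. Removing a column does not change correlations among the
  survivors, so the all-by-all matrix is computed once and masked — the
  result is identical to recomputing each iteration, at a fraction of the
  cost.

### GCI and its permutation null

GCI is defined over the replicate-averaged, per-condition matrix
(experiment-level computation would pseudoreplicate; it is available but
warned about). A gene with zero expression variance has an **undefined**
GCI, propagated as `NA` and counted — not coerced to 0, which would
assert "no association" that was never measured. At least 3 conditions
are required; with 2, any pairing is perfectly linear and r is ±1.

The null shuffles, per gene independently, the pairing between expression
values and growth rates and records one permuted r per gene. The
comparison reported (`permutationNullSummary()`) is descriptive: null
mean and sd, and the fraction of observed GCI outside mean ± 2 sd.

Per-condition fit strength is the R² of the simple OLS of CUB on the
condition's expression column (equal to squared Pearson r), on the stored
log scale — rank-transforming first is a defensible alternative the
package does not take, keeping the fit interpretable in the data's units.
Its Spearman correlation with growth rate uses exact enumeration for
n ≤ 9 (the t-approximation is invalid on tiny fixtures) and the
t-approximation otherwise.

Doubling time is `ln(2)/rate`. Note `ln(2)/1.42 = 0.488`, which rounds
to 0.49 though 0.48 sometimes appears in print via truncation; the
package rounds.

### The model battery

Four OLS models with CUB as response: mean expression only; GCI only;
additive; additive plus interaction. Adjusted R²,
`1 − (1 − R²)(n − 1)/(n − p − 1)`, is the comparison measure; unadjusted
R² is monotone non-decreasing along the nesting by construction, and the
tests assert that exactly. Predictors stay on their stored scales (log
mean expression; GCI raw) so coefficients keep their units; an optional
standardization reduces nonessential collinearity in the interaction
model. Genes with undefined GCI are excluded listwise from **all four**
models, so the adjusted R² values compare like with like. VIFs come from
the defining regression `VIF_k = 1/(1 − R²_k)`; with two predictors both
VIFs coincide, so reporting "the" VIF of the additive model is
unambiguous. A linear-vs-quadratic AIC comparison
(`linearVsQuadraticAIC()`) is the only nonlinearity check implemented.

### Group statistics

The t-tests are pooled-variance Student's tests (df = n₁ + n₂ − 2), as
"Student's t-test" implies; Welch is available. Over-representation
analysis is the hypergeometric upper tail `P(X ≥ k)` — standard ORA
semantics — with BH correction across all tested terms, an unusual but
deliberate default significance filter of **P ≤ 0.04** and q ≤ 0.05
(configurable), and odds ratios from the unconditional 2×2 cross-product
`(k(N−K−n+k))/((n−k)(K−k))` rather than a conditional MLE: reproducible
without iterative fitting. Infinite ORs from zero cells are reported
honestly; the Haldane–Anscombe 0.5 correction is an opt-in flag. The gene
universe is all genes with defined GCI in the analyzed matrix. Gene→term
tables are user-supplied; mapping to real GO/Entrez identifiers is an
adapter concern outside the package.

## The synthetic-data generator

The generator defines the study conditions every test runs under; its
defaults are fixed, not tuned per run.

- **Conditions**: 50 conditions, growth rates uniform on 0.07–1.42 1/h
  (the span typical of laboratory compendia, from late-stationary-like to
  fast aerobic growth), 2 replicates each (compendia averaging a few
  hundred experiments into ~100 conditions have ~2–3 replicates per
  condition), replicate rate jitter sd 0.02 1/h. Half the conditions are
  flagged ALE and 40% of the rest mutant/KO, mimicking the roughly
  103 → 48 → 28 attrition of full → non-ALE → wild-type subsets in real
  compendia.
- **Expression**: `e_gc = b_g + s_g·μ_c + ε`, `ε ~ N(0, 0.5²)`;
  baselines `N(3, 1.5²)` (log-TPM-like); slopes a two-component mixture,
  65% `N(−0.5, 0.3²)` and 35% `N(+0.8, 0.4²)`. The affine-in-growth
  model is the simplest under which GCI consistently estimates the sign
  of the planted coupling; the mixture proportions and means put the GCI
  mode near −0.3 with a long positive tail, the left-skewed shape real
  data show (most genes dilute out under rapid growth; ribosomal-type
  genes rise).
- **Sequences**: bias strength `β_g = softplus(1.0·z(b_g) + 0.5·z(s_g))`;
  within each synonymous family codon c is drawn ∝ `w(c)^β`. Softplus
  keeps β ≥ 0 while letting weakly coupled genes approach uniform usage;
  the 2:1 weighting of baseline over slope makes expression the stronger
  CUB predictor, matching the observed ordering of single-predictor
  models. Amino acids are uniform over the 18 multi-codon families
  (single-codon families carry no bias signal); genes are 100–400 codons
  plus ATG/TAA framing, so lengths are divisible by 3 by construction.
  An explicit `betaOverride` exists because softplus(0) = ln 2: exact
  neutrality (β = 0) must be requestable directly.
- **Annotations**: 40 terms of 20–120 genes; one planted term draws 80%
  of its members from positive-slope genes, the rest uniform.

What the generator does **not** emulate: count-level noise (TPM
estimation, mass-spec missingness), correlated gene programs (genes are
conditionally independent given growth rate), nonlinear growth responses,
compositional constraints on expression, GC/amino-acid composition
confounds, and phylogenetic structure. Passing tests therefore show the
estimators recover planted structure of this simple kind — not that real
compendia satisfy the model. On real data the expression→CUB R² values
are far lower (≈ 0.2–0.4) than on this clean generator (≈ 0.85), because
real CUB responds to much besides expression; the package's assertions
are about orderings and signs, which are scale-free.

## Numerical choices

- Geometric means in log space; oracle tests pin them to direct
  product-then-root on short sequences at 1e-12.
- Duplicate detection tolerance: `ρ ≥ 1 − tol − 1e-12` (see above).
- Spearman p-values: exact for n ≤ 9 without ties, t-approximation
  otherwise.
- Degenerate inputs error early and specifically: all-zero columns in
  normalization, zero pooled variance in t-tests, rank-deficient designs
  (naming the aliased columns), tied-rank-only Spearman input, fewer than
  3 conditions for GCI.
- All randomness (permutation, pruning, generation) is scoped: functions
  take explicit seeds, set them locally, and restore the caller's RNG
  state.

## Problem sizes

The test suite and the acceptance script run the full pipeline at 3,000
genes × 50 conditions — large enough for stable rank-recovery statistics
(Spearman standard error ≈ 0.02) and sub-minute runtimes on one core —
with module tests on matrices of tens to hundreds of rows.

## Known limitations

- The GCI is a linear-correlation summary; genes with non-monotone
  growth responses get attenuated or zero GCI by design.
- ORA treats terms independently; no term-hierarchy-aware (elim/weight)
  methods.
- tAI weights are consumed, not derived from tRNA gene copy numbers.
- Mechanistic population-genetic CUB models (e.g. ribosome-overhead-cost
  MCMC fits) are outside scope; the package consumes their scores like
  any other per-gene metric if supplied as a weight-free column.
- The GenBank reader is a minimal flat-file CDS extractor
  (simple/complement/join locations); exotic location operators and
  multi-record files are out of scope — use FASTA exports for those.

```{r session}
sessionInfo()
```
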