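---
title: "Cross-study mega-analysis of differential expression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study mega-analysis of differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megalfc)
```

## The problem and the approach

Case/control expression studies of the same disease rarely agree study
by study: platforms, tissues and populations differ, and single-study
differential expression lists replicate poorly. A *mega-analysis* pools
the individual-level data: each study contributes, per gene, a log2
fold change with its uncertainty, and the per-study effects are combined
with explicit modeling of between-study variation. This vignette
documents the statistical choices behind the package, in the order the
pipeline applies them.

## Preprocessing

Expression matrices arrive on unknown scales. `preprocess()` judges a
matrix linear-scale when its maximum exceeds 50 — log2 microarray or
RNA intensities essentially never reach that value while linear
intensities essentially always do — and applies `log2(x + 1)`; the
threshold is a flag-overridable heuristic and every decision is written
to the study log. Cross-sample normalization then equalizes per-sample
medians (default) or quantile-normalizes (limma). Both steps are
idempotent, so re-running the pipeline on processed data is harmless.

Cross-sample normalization assumes that *most genes are unchanged*
between samples. This matters for validation: a simulation that plants
the same shift in every gene violates the assumption, and median
scaling will (correctly) remove the shift. The package's calibration
and recovery simulations therefore run with `normalization = "none"` —
the generator already produces studies on a common scale — while the
log2-detection step is still exercised, because the generator emits
linear-scale values.

## Effect sizes

Per (gene, study): `y = mean(log2, case) − mean(log2, control)`, the
Welch-type standard error `se = sqrt(s²_case/n_case + s²_ctrl/n_ctrl)`
with unbiased per-arm variances, and `z = y/se`. The Welch form was
chosen because it requires no equal-variance assumption between arms
and is the standard estimator when none is stated; it is isolated in
one function should a moderated estimator ever be wanted (deliberately
out of scope — nothing in the pooling below depends on shrinkage).
A floor of `1e-6` on `se` keeps weights finite when a toy input has a
zero-variance arm; it is far below any real standard error on the log2
scale and only affects degenerate inputs. Genes missing from a study
simply contribute no record, so the number of pooled studies `k` varies
by gene.

`qq_points()` supports the standard diagnostic for whether a study's
z-scores are distributionally unremarkable: sorted observed z against
normal quantiles at plotting positions `(i − 0.5)/m` (one of several
accepted conventions; the choice is immaterial for m in the thousands).

## Pooling and heterogeneity

Fixed-effect pooling is inverse-variance weighting; the random-effect
model is DerSimonian–Laird, the method-of-moments estimator
`τ² = max(0, (Q − df)/C)`, `C = Σw − Σw²/Σw`, re-pooling with
`w* = 1/(se² + τ²)`. Three reporting rules matter:

* **Heterogeneity is a property of the collection, not of the chosen
  model**: `Q`, `df`, `I²` and `p–Q` are always computed from the
  fixed-effect weights, so the reported `I²` does not change when the
  random model is selected.
* **Model selection**: in `auto` mode the fixed model is used exactly
  when the truncated `I²` is 0 (`Q ≤ df`); otherwise random. The rule
  is deliberately binary rather than threshold-based (e.g. `I² > 50`):
  any excess between-study variance switches to the model that accounts
  for it.
* **Normal reference**: p-values and the 95% CI multiplier (1.959964)
  use the standard normal, the convention of inverse-variance pooled
  z-statistics; with k around 9 a t-reference would differ visibly, and
  the normal is what reproduces p-values of the 1e−9 order observed for
  strongly pooled effects.

With `k = 1` the "pooled" result is the study itself, `Q = 0`,
`I² = 0`, `p–Q = 1`.

## The partial mega-analysis

For each gene the `floor(k/2)` records with the largest `|y|` are
re-pooled (at least one study; 9 studies pool 4, 8 pool 4). Rounding
*down* is forced by the arithmetic of a 9-study collection reporting 4
pooled datasets. Ties on `|y|` break by smaller `se`, then by
`study_id` — an arbitrary but deterministic rule that makes the
selection invariant to input order. The partial analysis is a
sensitivity screen, not an unbiased estimator: selecting on `|y|`
inflates the pooled magnitude under the null and under homogeneous
signal alike, which is why both the full and the partial rows are
always reported side by side and neither replaces the other.

## Significance filter

`p < 1e−7` and pooled LFC strictly `> 0.49` or `< −0.74`: a more than
40% expression increase (log2 1.4 ≈ 0.485, printed as 0.49) or decrease
(log2 0.6 ≈ −0.737, printed as −0.74). The numeric asymmetry is the
asymmetry of the log scale, not two different fold-change criteria. The
thresholds are strict inequalities; boundary values fail. No
multiple-testing correction is applied at this stage — the raw-p
criterion at 1e−7 is itself far beyond a Bonferroni bound for a
genome-sized family; BH correction appears only in the enrichment
module. A gene's overall call is positive if *either* the full or the
partial analysis passes: a gene consistently shifted in half the
datasets is a positive finding of the sensitivity screen, and the
report keeps both rows so the reader sees which analysis carried it.

## Gene sets

`partition_sets` / `hypergeom_overlap` implement the set arithmetic and
the upper-tail hypergeometric overlap probability
`P(X ≥ n_overlap)`; the universe size is a mandatory part of the result
because the tail is meaningless without it (the default 20,000
approximates the protein-coding genome; any published overlap p-value
implies some such background, stated or not). `enrich()` is
over-representation in the Fisher/hypergeometric form — one tail per
GMT term, BH across terms — not a ranked (Kolmogorov–Smirnov-style)
GSEA; term collections are user-supplied GMT files, and the engine
makes no claim about any particular ontology snapshot.

## Moderator regression

Per gene, OLS of the per-study `y` on an intercept, total sample size,
study year, and region. Region is dummy-coded against the most frequent
level and tested as a whole factor by the nested-model F-test; numeric
moderators get t-based p-values and CIs at the residual degrees of
freedom. With few studies and many countries the raw design is
unidentifiable, so when the factor has more than `max_levels` (default
3) levels or any singleton level, labels are merged through a
configurable map (default: continents) and the merge is recorded in
`design_note`. The fit refuses designs with fewer than two residual
degrees of freedom and names the offending factor on rank deficiency.
Unweighted OLS is the default — the effect sizes enter as plain
responses — with `weighted = TRUE` for inverse-variance weighting.

## The synthetic generator

`simulation_config()` describes K independent studies: per-gene true
log2 fold change `θ_g`, optional between-study variance `τ²_g` (the
study-level deviation `δ_gs ~ N(0, τ²_g)` shared by a study's case
samples), within-arm per-sample SD `σ` on the log2 scale (Gaussian on
log2 = log-normal on linear scale), per-gene baselines, per-study arm
sizes, and per-(gene, study) Bernoulli dropout to exercise variable
`k`. Defaults mirror a realistic nine-study collection: the arm sizes
(18/20, 10/6, 30/24, 23/9, 22/135, 6/6, 10/10, 36/27, 16/19), six
countries and the 2008–2016 year span of the public COPD series the
pipeline was designed around; `σ = 0.5` and baseline 8 are typical log2
microarray values. Matrices are emitted on the linear scale so the
pipeline's own log2 detection runs. Seeding is hierarchical (one
sub-seed per study drawn from the master seed), making
`generate_study(cfg, i)` identical to the i-th element of
`generate_collection(cfg)` and the whole collection bit-reproducible;
the caller's RNG state is untouched.

What the generator does *not* emulate — and what green tests therefore
do not certify on real data: probe-level artifacts and probe→gene
collapsing, platform batch effects, count-based (RNA-seq) noise,
correlated genes, and case/control imbalance in variance. It validates
the statistics, not the upstream genomics.

## Problem sizes and numerical checks

The shipped validation uses desk-scale simulations chosen to make the
statistical bands meaningful: null calibration with 2,000 genes
(K = 9, n = 15/15, θ = 0, where the expected p < 0.05 rate band
0.035–0.065 is about ±3 binomial SDs), recovery with 500 genes at
θ = 0.51 (K = 9, n = 20/20, σ = 0.5), moderator calibration with 2,000
pure-noise genes, and exhaustive hypergeometric enumeration for all
universes up to 60. Estimator identities are checked to 1e−12 against
brute-force oracles and cross-checked against an independent
meta-analysis implementation. At θ = 0.51 the planted effect sits only
~0.4 pooled-SE above the 0.49 cutoff, so the *full* analysis alone
passes the filter for ~60–65% of genes by construction; the gene-level
call (full or partial) exceeds 95%, which is precisely the role of the
partial screen.

## Known limitations

* DerSimonian–Laird is the only τ² estimator (no REML/Paule–Mandel, no
  Hartung–Knapp adjustment) — by design, to keep the pooled inference
  the plain normal-reference form described above.
* Gene matching across studies is exact upper-cased symbol equality;
  probe-level handling is upstream of this package.
* The GEO series-matrix reader is a best-effort convenience for the
  common dialect and is flagged experimental.
* The partial mega-analysis is a biased selection procedure; its
  p-values are screening p-values and should be read together with the
  full-analysis row.
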