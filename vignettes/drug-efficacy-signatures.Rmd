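---
title: "Deriving and validating drug efficacy signatures with drugsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating drug efficacy signatures with drugsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsig)
```

## The problem and the model

Pharmacogenomic cell-line screens pair baseline transcriptomes with a
drug-response readout — here the activity area above the dose–response
curve, called AUC and oriented so that **higher values mean greater
sensitivity**. `drugsig` implements a correlation-based pipeline that turns
such a screen into per-drug *drug efficacy signatures* and per-sample
*efficacy scores*:

1. **Signature derivation.** For one drug, draw 80% of the cell lines
   without replacement, compute each gene's Spearman correlation between
   expression and AUC over the draw, and mark the genes in the top and
   bottom 3% of the correlation ranking. Repeat 1000 times. Genes that sit
   in a tail in at least 90% of the draws form the signature: the positive
   tail is the up-regulated set (expression rises with sensitivity), the
   negative tail the down-regulated set.
2. **Single-sample scoring.** A sample's expression profile is reduced to a
   score against the signature by `singscore()`: genes are ranked within
   the sample, the mean rank of each signature set is normalized by its
   theoretical extremes and centered, and the up and down components are
   summed. The score uses only within-sample ranks, so it is invariant to
   any strictly increasing transform of the profile — normalization
   differences between samples cannot move it. `stingscore()` replaces the
   whole-profile ranking by the percentile of each signature gene among a
   small panel of stably expressed anchor genes, which additionally makes
   scores comparable across datasets whose gene coverage or background
   distributions differ.
3. **Prediction models.** Per drug, the score is the single input feature
   to five models — linear and quadratic least squares, and
   epsilon-regression SVMs with linear, polynomial and radial kernels —
   selected and assessed by 3-fold cross-validation repeated 20 times
   (RMSE, MAE, R², and BIC for the regression pair).
4. **Validation.** Agreement between predictions and observed response in
   independent datasets is measured with Spearman's ρ and the concordance
   index (CI); each drug is classified **high** confidence if any test
   dataset reaches ρ ≥ 0.4 or CI ≥ 0.65, **low** if every dataset stays
   below ρ < 0.3 and CI < 0.6, and **medium** otherwise.
5. **In-vivo validation.** Xenograft response is summarized per mouse by
   the normalized tumor response, NTR = V\_min / V\_inj: the smallest
   tumor volume at or after the first drug injection divided by the volume
   at injection. NTR ∈ (0, 1], equals 1 exactly for a tumor that never
   shrinks, and a working signature's scores are strongly *anti*-correlated
   with per-model median NTR.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `resample_fraction` | 0.8 | fraction of cell lines per resampling draw |
| `n_resamples` | 1000 | resampling runs per drug |
| `tail_fraction` | 0.03 | fraction of genes per correlation tail |
| `min_frequency` | 0.90 | tail-membership frequency needed for selection (inclusive) |
| `cpm_threshold`, `min_fraction` | 2, 0.10 | CPM filter: CPM strictly above 2 in at least 10% of samples |
| `offset` | 1 | additive offset inside `log2(RPKM + offset)` |
| tier thresholds | 0.4 / 0.65, 0.3 / 0.6 | high and low confidence cutoffs on ρ / CI |

Interpretation choices behind these defaults, where the conventions in the
field differ, were fixed once and are configurable:

- **Log transform.** "log RPKM" is implemented as base-2 with an additive
  offset of 1 inside the logarithm, the dominant RNA-seq convention, which
  maps zero counts to exactly 0.
- **Filter boundaries.** "CPM > 2" is strict; "at least 10% of samples"
  is inclusive, implemented as `ceil(min_fraction * n)`. Library sizes are
  the column sums of the *pre-filter* matrix, so filtering is idempotent.
- **Selection frequency.** The frequency cutoff is inclusive
  (≥ `min_frequency`): a gene selected in exactly 900 of 1000 runs is in.
- **Tail size.** `k = max(1, round(tail_fraction * n_genes))`; ties in ρ at
  the tail boundary are broken by the stable input gene order, making the
  derivation deterministic under a fixed seed.
- **Undefined correlations.** A gene constant within a draw has no defined
  ρ there and is simply absent from both tails of that run.
- **Concordance index ties.** Pairs with tied observed response are
  excluded; tied predictions score 0.5.
- **NTR orientation.** The ratio is taken as V\_min / V\_inj ∈ (0, 1]
  (larger = worse response), the orientation under which efficacy scores
  are anti-correlated with NTR; `invert = TRUE` gives the reciprocal
  reading. The injection-day measurement itself counts as "after the
  injection", which pins NTR of a monotonically growing tumor at exactly 1.
- **Cross-validation splits.** Each repeat draws one seeded partition into
  three near-equal folds which is shared by every method and
  hyperparameter set, so methods are compared on identical splits. R² is
  the squared Pearson correlation of held-out predictions with
  observations.

## What the synthetic generator emulates

`generate_cohort()` plants the structure the pipeline assumes: each sample
carries a latent sensitivity `s ~ N(0, 1)`; AUC is
`clamp(0.5 + 0.15 s + ε, 0, 1)` with `ε ~ N(0, 0.05)`; planted up/down
genes move by `± effect_size · s` (default 1.5 log2 units per latent SD)
around uniform baselines in [2, 8] log2 RPKM with expression noise SD 0.3;
all other genes are pure noise. Counts are Poisson draws whose per-sample
expected totals equal library sizes drawn from [5×10⁵, 10⁶], so converting
counts back to log RPKM recovers the expression matrix up to Poisson noise
and a per-sample constant. The default cohort — 1000 genes, 60 samples,
20 + 20 planted genes — is the reference condition for every end-to-end
test, with derivation run at 200 resamples to keep the default test suite
fast; these sizes were chosen as the smallest at which the planted tails
separate cleanly from the null.

`generate_batch_shifted_pair()` emulates the cross-dataset scoring problem:
the same cohort profiled twice, with the second dataset's *background*
genes shifted and scaled while planted signature genes and a panel of five
near-constant anchor genes (log-scale SD 0.01, baselines spread evenly over
[3, 7]) keep their calibration. This is precisely the stingscore premise:
the displaced background moves whole-profile ranks — so naive singscore
component means drift between the datasets — while anchored percentiles are
untouched and stingscore stays comparable.

`generate_growth_curves()` produces twice-weekly caliper measurements:
exponential growth from engraftment, first injection at the first
measurement ≥ 200 mm³, then for responders a ~3-week exponential regression
(mean shrink rate `decay_rate`, so more sensitive models reach lower NTR)
followed by regrowth, and for resistant tumors continued monotone growth.

What the generator deliberately does **not** model: RNA-seq overdispersion
beyond Poisson, correlated multi-drug response structure, batch effects on
the planted genes themselves, censored or irregular in-vivo follow-up.
Passing tests therefore demonstrate the pipeline's correctness and its
behavior under its own assumptions, not performance on real screens.

## Null behavior of the resampling selection

One property of the derivation deserves emphasis. Because the resampling
draws 80% of the cohort, any two draws share about two-thirds of their
samples, and per-gene correlations are strongly dependent across runs: the
conditional spread of a subsample ρ around the full-cohort ρ
(≈ √(1/(m−1) − 1/(n−1)) ≈ 0.066 at n = 60, m = 48) is small compared with
the top-3% boundary of the null correlation distribution (≈ 0.245 at 1000
genes). A null gene whose full-cohort correlation lands beyond that
boundary tends to *stay* in the tail across runs. Consequently, on a
cohort with no planted signal the derivation does not return an empty
signature: the acceptance script measures a handful of selected genes
(≈ 1% of the panel) per null cohort. The resampling frequency filter
suppresses genes near the tail boundary, not genes that are lucky in the
cohort as a whole; with real screens this residual false-positive set is
part of the method's operating characteristics, and the planted-signal
tests show it stays an order of magnitude below a true signal's recall.

## Numerical and degenerate-input conventions

- Spearman correlations use average ranks throughout; constant vectors
  yield `NA` with a warning rather than an arbitrary value.
- `singscore()` with a gene set covering the whole profile would divide by
  zero; the component is reported as 0 with a warning.
- Constant scores make least-squares fits intercept-only (with a warning)
  and SVM fits an error.
- `stratify_by_score()` uses type-7 (linear interpolation) quantiles; with
  constant scores all samples collapse into one tier, with a warning.
- An exact regression fit (RSS = 0) reports BIC = −∞ with a warning.
- Signature derivation enforces disjoint up/down sets; in degenerate
  threshold settings a gene qualifying for both tails goes to the tail
  with the higher frequency, ties resolved by the sign of its median ρ.

## Known limitations

- The confidence-tier rule is applied exactly as stated; two drugs in the
  packaged published table (BIBW2992, Temsirolimus) carry a printed test
  correlation of exactly 0.40 yet a printed *medium* label, so the rule
  reproduces 26 of the 28 printed labels and classifies those two as
  *high*. The package applies the rule rather than special-casing the
  boundary.
- SVM hyperparameter grids are small logarithmic defaults; the methods are
  standard epsilon-regression and no claim is made that the grids are
  optimal.
- The pipeline evaluates rank agreement (ρ, CI) across datasets; absolute
  AUC calibration across screens is out of scope, as inter-dataset
  intercept shifts are expected.
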