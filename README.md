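# drugsig

Gene-expression signatures of drug efficacy from pharmacogenomic screens,
and per-sample response prediction built on them.

`drugsig` is for computational biologists who have (or can emulate) a
cell-line screen pairing baseline transcriptomes with a drug-response
readout — the activity area above the dose–response curve (**AUC**,
oriented so higher = more sensitive) — and want to:

1. derive, per drug, an **efficacy signature**: an up-regulated gene set
   (expression positively correlated with sensitivity) and a down-regulated
   set, selected by a resampling procedure — 80% of cell lines drawn 1000
   times, per-gene Spearman correlation ρ(expression, AUC) per draw, and
   genes kept when they land in the top or bottom 3% of the correlation
   ranking in at least 90% of the draws;
2. reduce any expression profile to a **drug efficacy score** with the
   rank-based single-sample method *singscore* — for a gene set of size
   *m* in a profile of *n* genes, the centered normalized mean rank
   (r̄ − r_min)/(r_max − r_min) − ½ with r_min = (m+1)/2 and
   r_max = (2n−m+1)/2, summed over the up and (rank-reversed) down sets —
   or its anchor-based variant *stingscore*, which ranks signature genes
   against a panel of stably expressed genes for cross-dataset
   comparability;
3. fit and cross-validate per-drug **prediction models** (linear,
   quadratic, and linear/polynomial/radial-kernel SVM regression; 3-fold
   CV × 20 repeats; RMSE, MAE, R², BIC);
4. **classify drugs by confidence** from per-dataset Spearman ρ and
   concordance index (CI): *high* if ρ ≥ 0.4 or CI ≥ 0.65 in at least one
   test set, *low* if ρ < 0.3 and CI < 0.6 everywhere, *medium* otherwise;
5. validate against xenograft experiments via the **normalized tumor
   response** NTR = V_min/V_inj ∈ (0, 1] per mouse (1 = no shrinkage) and
   its anti-correlation with efficacy scores.

A first-class synthetic-data module generates cohorts with planted
sensitivity/resistance gene programs, batch-shifted replicate datasets with
stable anchor genes, and responder/resistant tumor growth curves, so the
entire pipeline is testable end-to-end without any external download. A
published table of cross-dataset validation correlations for 28 drugs ships
as a worked-example fixture (`reported_validation_correlations()`).

## Worked example

```r
library(drugsig)

# a synthetic screen: 1000 genes x 60 cell lines, 20 + 20 planted genes
cohort <- generate_cohort(synthetic_config(seed = 42))

# derive the drug's efficacy signature (200 resampling runs)
params <- signature_params(n_resamples = 200, seed = 43)
freq   <- resample_correlations(cohort$expr,
                                setNames(cohort$response$drugA,
                                         cohort$response$sample_id),
                                params)
sig <- derive_signature(freq, params, "drugA")
sig
#> drug_signature for drugA: 22 up, 22 down genes

# score every sample and check the association with observed response
scores <- score_matrix(cohort$expr, sig)
spearman_rho(scores$total_score, cohort$response$drugA)
#> [1] 0.931

# cross-validated prediction models (score -> AUC)
cv <- cross_validate(scores$total_score, cohort$response$drugA,
                     methods = c("linear", "quadratic"),
                     k = 3, repeats = 20, seed = 44)
cv
#> cv_report: 3-fold x 20 repeats
#>      method  rmse_mean   mae_mean   r2_mean       bic
#> 1    linear 0.04812510 0.03829253 0.9037179 -361.2565
#> 2 quadratic 0.04890354 0.03905688 0.9016981 -357.9277

# confidence tiers from the packaged published correlations
tab   <- reported_validation_correlations()
tests <- tab[tab$dataset != "GRAY", ]          # exclude the training screen
tiers <- vapply(split(tests, tests$drug),
                function(d) classify_confidence(data.frame(rho = d$rho)), "")
table(tiers)
#> tiers
#>   high medium
#>     22      6
```

The derived signature recovers the planted 20 + 20 gene programs (with a
couple of borderline extras), the signature score orders cell lines by
their observed response at ρ ≈ 0.93, and a linear model predicts held-out
AUC with CV RMSE ≈ 0.05 on the [0, 1] AUC scale. Applied to the published
correlation table, the stated tier rule reproduces 28 medium-or-better
drugs (see the methods vignette for the two boundary rows where the
printed label differs from the stated rule).

For growth-curve analysis:

```r
curves <- generate_growth_curves(5, responder = TRUE, seed = 1)
sapply(curves, normalized_tumor_response)   # deep regression: NTR << 1
```

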