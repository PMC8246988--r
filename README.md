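# tractnorm

Normative univariate and multivariate distances for white-matter tract
metrics, and their association with epilepsy duration in unilateral
temporal lobe epilepsy (TLE).

## What it does, and for whom

Given a demographics table and a table of tract-mean fractional anisotropy
(FA) for ten limbic tracts (bilateral ATR, CG, CH, fornix, UF) —
or a synthetic cohort generated in-package — `tractnorm` quantifies each
subject's deviation from a healthy-control reference and relates it to
disease variables. It is intended for neuroimaging statisticians working
with tract-level summary metrics; it starts *after* image processing (no
NIfTI/DICOM/tractography handling).

The pipeline:

1. **Covariate removal** — per-tract robust regression `FA ~ age + sex`
   (Huber M-estimator, IRLS, `k = 1.345`, MAD scale), residuals FAr.
2. **Univariate distances** — per tract, the robust z-score: the median of
   `(x − x̄_sub)/s_sub` over 1,000 random subsamples of 24 controls
   (leave-one-out for control subjects).
3. **Multivariate distances** — per hemisphere, the robust Mahalanobis
   distance

   D_M = sqrt( (x − μ)ᵀ C⁻¹ (x − μ) ),

   with μ and C re-estimated per 24-control subsample, C a Ledoit–Wolf
   linear shrinkage covariance, and the median over 1,000 subsamples
   reported. Distances are relabelled ipsi-/contralateral to each
   patient's epileptogenic focus.
4. **Inference** — one-tailed Spearman correlations with epilepsy duration
   via t = ρ·sqrt(n−2)/sqrt(1−ρ²) on n−2 df (z-scores hypothesised
   negative, distances positive), Bonferroni-corrected (h = 10
   univariate, h = 2 multivariate); critical threshold
   ρ* = t*/sqrt(n−2+t*²), e.g. ρ* = −0.44 at n = 33, h = 10.
5. **Onset extrapolation** — Huber regression D_M = β₀ + β₁·duration on
   patients; log β₀ scored against the 56 log control distances
   (subsample-median z, 54 of 56).
6. **Auxiliary tests** — Yates χ² and two-sample t-tests for cohort
   comparisons; one-tailed t-tests of distances vs ILAE surgical outcome;
   Lilliefors (Monte-Carlo p) and Mardia normality gates.
7. **Robustness** — consistency κ: the percentage of 1,000 random
   subsamples of m = 30 patients whose duration correlation stays
   Bonferroni-significant.

See `vignettes/normative-distances.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(tractnorm)

cfg <- pipeline_config(generator = generator_config(),  # 28/33/33 cohort
                       seed = 1, out_dir = "tractnorm_output")
res <- run_pipeline(cfg, quiet = TRUE)

subset(res$associations, measure_id %in% c("md_ipsi", "md_contra"))
```

```
   measure_id     group    rho  n p_one_tailed significant_bonferroni
11    md_ipsi  left_tle 0.5344 33     6.78e-04                   TRUE
12  md_contra  left_tle 0.2279 33     1.01e-01                  FALSE
23    md_ipsi right_tle 0.4245 33     6.91e-03                   TRUE
24  md_contra right_tle 0.0739 33     3.41e-01                  FALSE
25    md_ipsi  combined 0.5061 66     7.27e-06                   TRUE
26  md_contra  combined 0.1567 66     1.04e-01                  FALSE
```

On this synthetic cohort (whose generator encodes a negative ipsilateral
FA-duration trend with patient-specific tract loadings), the ipsilateral
hemispheric distance correlates positively with duration in both patient
groups and survives Bonferroni correction; the contralateral distance does
not. The onset extrapolation

```r
res$onset$ipsilateral[c("beta0", "z_intercept", "p_two_tailed")]
#> beta0 1.995   z_intercept -0.111   p_two_tailed 0.912
```

shows the extrapolated distance at duration zero is indistinguishable from
the control distance distribution (as it should be here: the generator's
deficit grows from zero with duration). The consistency report

```r
subset(res$consistency, measure_id == "md_ipsi")[, c("group", "kappa")]
#>        group kappa
#> 11  left_tle 100.0
#> 23 right_tle  92.3
```

says the ipsilateral-distance association is significant in (nearly) every
random 30-of-33 patient subsample. All outputs are also written as CSV/JSON
to `out_dir`, with a `run_manifest.json` recording every seed.

A command-line wrapper is installed with the package
(`inst/cli/tractnorm.R`): `run`, `synth` and `validate` subcommands over
the same functions.

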