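# twostageval

Conditionally unbiased inference for the sensitivity of a diagnostic
classifier selected at the interim analysis of a two-stage validation study.

## The problem

A validation study starts with K candidate binary classifiers (biomarkers,
or yes/no questionnaire items). Classifier *i* is evaluated on *n*₁ᵢ known
cases at stage 1, giving true-positive counts *X*ᵢ ~ Bin(*n*₁ᵢ, *s*ᵢ)
independently, where *s*ᵢ is its true sensitivity. A classifier is dropped
for futility unless *X*ᵢ ≥ *c*ᵢ for a fixed cut-off *c*ᵢ; if none survives,
the study stops. The survivors are ranked by a pre-specified score
(estimated sensitivity by default; balanced accuracy for questionnaire
studies), ties going to the smaller index, and only the top-ranked
classifier *M* proceeds to stage 2, where *Y* ~ Bin(*n*₂, *s*_M) on *n*₂
further cases.

Because *M* had to look good at stage 1 to get selected, the pooled MLE
(*X*_M + *Y*)/(*n*₁_M + *n*₂) is biased high, and confidence intervals and
tests built on it are anti-conservative. The package computes the
**UMVCUE** — the uniformly minimum variance conditionally unbiased
estimator, obtained by Rao–Blackwellizing the unbiased stage-2 estimate
*Y*/*n*₂ against the complete sufficient statistic, conditional on the
selection event:

  s̃_M = E[ Y/n₂ | Z, selection ]
      = Σ_y (y/n₂) C(n₂, y) C(n₁_M, z₁ − y)  /  Σ_y C(n₂, y) C(n₁_M, z₁ − y),

where z₁ = x_M + y is the pooled count and the sums run over the
*restricted* hypergeometric support: those y for which x_M = z₁ − y both
passes the futility cut-off (x_M ≥ ⌈c_M⌉) and still beats the observed
runner-up under the ranking rule (a score tie being admissible only when
the selected index is smaller). When the restricted support reaches the
unrestricted hypergeometric maximum, the UMVCUE *equals* the MLE — a
built-in diagnostic that selection exerted no bias.

Around the point estimate the package provides:

* **exact conditional (Sill–Sampson type) intervals**, inverting the
  conditional distribution of Z₁ given the selection event (equal or
  length-optimised α-split), which are conservative under selection;
* **Clopper–Pearson** exact binomial intervals (selection-ignoring, for
  comparison);
* a **selection-aware percentile bootstrap** whose replicates must re-pass
  the futility and ranking conditions;
* interval-backed **one-sided tests** of H₀: s_M ≤ s\* with conditional and
  unconditional operating characteristics;
* an approximate **median-unbiased estimate** from the half-probability
  roots of the conditional tails;
* simulation drivers (`estimator_study`, `coverage_study`), a correlated
  binary generator (`rcorrbin`, latent-Gaussian thresholding with per-pair
  solved latent correlations), and the Fisher's-exact-test cut-off /
  balanced-accuracy machinery for family-history questionnaire (FHQ) style
  studies (`fisher_threshold`, `fhq_analyze`).

## Worked example

Two classifiers, 50 stage-1 cases each, futility cut-offs of 35 (a known
comparator of sensitivity 0.70), 50 stage-2 cases. Classifier 2 scores
38/50 at stage 1, survives alone, and scores 32/50 at stage 2:

```r
library(twostageval)
d   <- two_stage_design(n1 = c(50, 50), c = c(35, 35), n2 = 50)
fit <- twostage(x = c(30, 38), y = 32, design = d)
fit
#> Two-stage validation trial
#>   selected classifier M = 2 (of K = 2; L = 1 survivors)
#>   stage 1: 38/50   stage 2: 32/50   pooled z1 = 70
#>   restricted support of Y (set A'): {20, ..., 35}
#> Estimates of the selected classifier's sensitivity:
#>    mle stage1 stage2 umvcue
#> 0.7000 0.7600 0.6400 0.6691
```

The pooled MLE is 0.700, but the selection event truncates the support of
*Y* at 35 (a stage-1 count below 35 would have stopped the trial), and the
bias-corrected UMVCUE is 0.669 — between the optimistic pooled estimate and
the noisy stage-2-only 0.640. Exact intervals tell the same story:

```r
ss_ci(fit)                               # accounts for selection
#> 95% Sill-Sampson exact conditional interval: (0.5316, 0.7755)
confint(fit, method = "clopper-pearson") # ignores selection
#> 95% Clopper-Pearson exact interval: (0.6002, 0.7876)
```

For a questionnaire study, `fhq_analyze()` runs the whole pipeline per
condition (Fisher cut-offs with fixed control margins, balanced-accuracy
ranking, UMVCUE and intervals) on a per-question table such as the packaged
synthetic fixture `inst/extdata/fhq_synthetic.csv`.

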