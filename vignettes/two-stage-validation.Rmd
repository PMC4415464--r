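---
title: "Conditionally unbiased inference after interim selection in two-stage validation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditionally unbiased inference after interim selection in two-stage validation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostageval)
```

## The model and the selection event

A two-stage validation study evaluates $K$ candidate binary classifiers on
known cases. At stage 1, classifier $i$ yields a true-positive count
$X_i \sim \mathrm{Bin}(n_{1i}, s_i)$, independently across classifiers,
where $s_i$ is its true sensitivity. Three design elements are fixed before
any data are seen:

* **futility cut-offs** $c_i \ge 0$: classifier $i$ stays in contention only
  if $X_i \ge c_i$ (for integer counts, $X_i \ge \lceil c_i \rceil$); if no
  classifier passes, the study stops at the interim analysis;
* a **ranking rule**: survivors are ordered by a score $r(x; \lambda_i)$,
  strictly increasing in the count, with exact ties resolved in favour of the
  smaller index. The rule must also be expressible in *dominance* form: the
  event $r(x_i;\lambda_i) \ge r(x_j;\lambda_j)$ is equivalent to
  $x_i \ge d(x_j; \lambda_i, \lambda_j)$, with a bound depending on $x_j$
  and constants only. The default is the sensitivity ranking
  $r = x/n_1$, $d = n_{1i} x_j / n_{1j}$; the balanced-accuracy ranking used
  by questionnaire studies absorbs the fixed specificities into the
  constants. `ranking_rule()` cross-checks a user-supplied score/dominance
  pair over the whole achievable grid at construction, because the
  restricted support below silently depends on their agreement;
* a **stage-2 size** $n_2$ that does not depend on the stage-1 data.

The top-ranked survivor $M$ alone is validated at stage 2:
$Y \sim \mathrm{Bin}(n_2, s_M)$, independent of stage 1. All inference in
this package is *conditional on the trial continuing* (the selection event
$Q$): when every classifier fails its cut-off, the candidates have been
found inadequate and no estimate of their performance is produced —
`twostage()` returns a typed `"twostage_stopped"` object rather than an
error. Randomized tie-breaking is deliberately unsupported: no conditionally
unbiased estimator exists under it.

## The UMVCUE and its restricted support

The stage-2 proportion $Y/n_2$ is exactly conditionally unbiased for $s_M$
but wastes the stage-1 information. Rao–Blackwellizing it against the
complete sufficient statistic (the pooled count $Z_1 = X_M + Y$ together
with the other survivors' stage-1 counts) gives the uniformly minimum
variance conditionally unbiased estimator
$\tilde s_M = E[Y/n_2 \mid \mathbf{Z}, Q]$. Conditional on $Z_1 = z_1$
alone, $Y$ is hypergeometric with support
$\{\max(0, z_1 - n_{1M}), \dots, \min(z_1, n_2)\}$; conditioning on $Q$
truncates that support from above, because $x_M = z_1 - y$ must

1. pass the futility cut-off, $x_M \ge \lceil c_M \rceil$, and
2. beat the observed runner-up's count $z_2$ under the ranking rule, a tie
   being admissible only when the selected index is smaller than the
   runner-up's.

Only the runner-up constrains the support: the ranking (score with index
tie-break) is a total order, so outranking the second-ranked survivor
implies outranking all lower-ranked ones, which enter only through the
conditioning event being satisfied by their observed values. With a single
survivor only the futility bound applies. The estimator is then a ratio of
hypergeometric-weighted sums over the restricted support; the package
evaluates the weights in log space (`lchoose` + normalisation by the
maximum), since raw binomial coefficients overflow double precision once
the sample sizes reach the hundreds.

Two structural facts are worth internalising, and both are tested
exhaustively:

* when the restricted support still reaches $n_2$, the UMVCUE *equals* the
  pooled MLE — the method itself reports when selection exerted no bias;
* the conditional expectation depends on the data only through the
  conditioning class, not on the unknown sensitivities. The test suite
  enumerates every outcome of a grid of small designs ($K \le 3$,
  $n_{1i} \le 6$, $n_2 \le 6$, covering equal and unequal sizes, zero and
  positive cut-offs and both index orders of selected vs runner-up) and
  checks the implementation against the brute-force conditional expectation
  on every reachable class, at several enumeration sensitivities, to
  $10^{-12}$ relative tolerance. The design grid is a representative sample
  of that space (cut-offs are real-valued, so the space itself is
  unbounded); within each design the enumeration is complete.

Fractional dominance bounds are turned into integer count bounds by ceiling
when a tie is admissible and floor-plus-one when it is not, then nudged
against the score function itself to be robust to floating-point edge
cases. A single-point support returns the forced value rather than 0/0.

## Interval estimation

**Exact conditional (Sill–Sampson type) intervals.** The conditional
distribution of $Z_1$ given the selection event is
$f(z_1 \mid s) \propto h(z_1)\, s^{z_1} (1-s)^{n_{1M}+n_2-z_1}$, with
$h(z_1)$ the sum of the hypergeometric weights over the restricted support
at that $z_1$. The two-sided interval solves
$P(Z_1 \ge z_{\mathrm{obs}} \mid s) = \alpha_1$ for the lower bound and
$P(Z_1 \le z_{\mathrm{obs}} \mid s) = \alpha_2$ for the upper, with
$\alpha_1 + \alpha_2 = \alpha$ (equal split by default). Both tails are
monotone in $s$; the roots are found by bracketed root-finding on
$s \in [10^{-10}, 1-10^{-10}]$ with absolute tolerance $10^{-9}$, and a
bound is clamped to 0 or 1 when the observed count sits at the support
minimum or maximum. When the conditioning is vacuous ($K = 1$, $c = 0$) the
construction coincides with Clopper–Pearson exactly, a property the tests
assert across the count range. The *optimised* variant chooses $\alpha_1$
to minimise the length by golden-section search (tolerance
$10^{-4}\alpha$); the equal split is the default because the optimised
search multiplies the computational cost while the simulations show only a
marginal width gain.

**Clopper–Pearson** intervals around the pooled MLE come from the beta
closed form; they ignore the selection and are included as the comparator.

**Selection-aware bootstrap.** Each replicate redraws the selected
classifier's stage-1 count as $\mathrm{Bin}(n_{1M}, x_M/n_{1M})$ —
distributionally identical to resampling the individual binary responses
with replacement — and is *accepted* only if it passes the futility cut-off
and still beats the original observed runner-up under the ranking rule
(mirroring the conditioning event, with the original tie convention);
stage-2 responses are resampled likewise and the chosen estimator is
recomputed with the original runner-up value. The interval is the
type-7 percentile interval over the accepted replicates; the acceptance
rate is always reported, and a zero acceptance rate after a capped number
of attempts is a (loud) numerical error.

**Median-unbiased estimate.** The half-probability equations
$P(Z_1 \ge z_{\mathrm{obs}} \mid s) = 0.5$ and
$P(Z_1 \le z_{\mathrm{obs}} \mid s) = 0.5$ give two roots; the package
returns their midpoint. The midpoint is an interpretive choice (the two
roots, not their combination, are what the half-probability definition
pins down); the roots are attached as an attribute so a user can make a
different choice.

## Hypothesis testing

The one-sided test of $H_0\!: s_M \le s^\*$ rejects when the one-sided
$(1-\alpha)$ lower confidence bound exceeds $s^\*$ — strictly, so a
boundary tie favours $H_0$, consistent with the exactness claims. The
exact conditional bound spends the full $\alpha$ on the lower tail.
`operating_characteristics()` estimates, by simulation over a grid of
$s^\*$, the conditional type-I error
$P(\text{reject} \mid s_M \in S_0, Q)$ and its unconditional counterpart
$P(\text{reject}, s_M \in S_0)$ (a stopped trial never rejects), and the
analogous powers; a probability whose conditioning event is empty in the
simulation — e.g. "power" when every candidate is null — is reported as
`NA` rather than zero, since it is undefined rather than small. The same
simulated trials are reused across the grid, as when tracing an
operating-characteristic curve.

## Simulation drivers and their conventions

`estimator_study()` reports conditional bias and MSE over *continuing*
replicates, with the total replicate count as the denominator convention
for $P(\text{continue})$, and both counts in the output so either
convention can be inspected. The closed form
$P(\text{continue}) = 1 - \prod_i P(\mathrm{Bin}(n_{1i}, s_i) <
\lceil c_i \rceil)$ is printed alongside as an analytic cross-check.
`coverage_study()` draws replicates *until* the requested number of
continuing trials is reached, because intervals exist only for continuing
trials and the published comparisons are denominated that way. Both
drivers de-duplicate expensive conditional computations over the
conditioning class $(M, z_1, \text{support bound})$ — the estimator and the
exact interval depend on the data only through that class — which is what
makes $10^5$-replicate studies take seconds; bootstrap intervals are *not*
de-duplicated, so each trial keeps its own resampling noise. Monte-Carlo
standard errors accompany every point summary. Identical seeds give
bit-identical tables.

Default study sizes follow the published comparisons: $10^5$ replicates
for bias/MSE tables, $10^4$ continuing trials for coverage tables, and a
reduced $2{,}000 \times B{=}2{,}000$ scale for the bootstrap coverage
comparison, whose cost per trial is two orders of magnitude above the
cached exact methods and whose undercoverage signal is unambiguous at that
scale.

## Correlated classifiers

Real questionnaire items are not independent (a respondent answering "yes"
to a detailed family-history item logically answers "yes" to its parent
item). `rcorrbin()` generates correlated binary data by thresholding a
latent multivariate normal, solving each pair's latent correlation from the
bivariate-normal orthant equation so that the *binary* correlations match
the target (Emrich–Piedmonte construction). The orthant probability is
computed by one-dimensional quadrature of
$\phi(x)\,\Phi((\rho x - b)/\sqrt{1-\rho^2})$, so no additional dependency
is required; per-pair root-finding uses tolerance $10^{-6}$. Infeasible
margin/correlation pairs (outside the Fréchet bounds) are rejected by name;
a latent matrix that fails positive definiteness after pairwise solving is
ridged to the nearest usable correlation matrix. The packaged 11-item
stage-1 correlation matrix (`fhq_correlations()`) has mean absolute
pairwise correlation 0.07 — small enough that simulations patterned on it
leave the UMVCUE's bias an order of magnitude below the MLE's selection
bias, which is the robustness statement the generator exists to check.

## Questionnaire (FHQ) studies

`fhq_analyze()` reverse-engineers the common questionnaire selection
procedure into the threshold-plus-ranking framework:

* **Fisher cut-offs.** With the control-arm results (FP, TN) held fixed by
  conditioning — essential, since letting them vary would make the cut-off
  depend on the case counts and break the conditional framework —
  `fisher_threshold()` returns the smallest $c$ such that the two-sided
  Fisher's exact p-value is below $\alpha$ for *every* count from $c$
  upward, by exhaustive scan. Only the upper tail qualifies a question: a
  count significant for being unusually *low* implies a poor sensitivity
  and is not of interest. The minimum-likelihood two-sided p-value (the
  mainstream software convention) is the default; a mid-p switch is
  exposed because published analyses do not always state their convention.
  An unattainable cut-off is returned as `Inf` (the question can never
  qualify). $\alpha \ge 1$ qualifies every count, including tables whose
  p-value is exactly 1.
* **Balanced-accuracy ranking**, with the fixed specificities absorbed into
  the rule constants, so the dominance bound needed by the restricted
  support is available in closed form.
* **Stage concordance.** `stage_concordance_chisq()` is the conventional
  continuity-corrected chi-squared comparison of stage-wise sensitivities
  (the correction is what standard software reports for 2×2 tables, and
  the switch is exposed). It is a supporting diagnostic only — the worked
  analyses show it is far too conservative to detect selection bias that
  the UMVCUE/MLE comparison exposes directly.

The packaged fixture `inst/extdata/fhq_synthetic.csv` is a **synthetic**
reconstruction of a four-condition questionnaire study: the per-question
stage-1 tables are invented, with the selected questions' stage totals
chosen to echo a real validation study (19/26 then 14/22 for the
breast-cancer-like condition) and the runner-up placed so that the support
restriction binds for exactly that condition. It exercises both branches
of the no-bias diagnostic: three conditions with UMVCUE = MLE, one with
UMVCUE < MLE. Questions flagged `excluded` (sparse responses) are dropped
before threshold derivation. Exactly equal balanced accuracies did not
occur in the data the fixture imitates; the smallest-index rule would
apply if they did.

## What the simulations do and do not show

The synthetic-data generator draws independent binomial counts under the
stated design — exactly the model the estimator is derived under. Passing
tests therefore demonstrate correctness of the implementation and the
finite-sample operating characteristics *under the model*: conditional
unbiasedness of the UMVCUE, conservative coverage of the exact conditional
intervals, undercoverage of the naive bootstrap around the MLE, inflation
of the MLE's conditional type-I error. They do not certify behaviour under
model violations; the correlated-binary study probes one realistic
violation (dependent items) and shows only modest degradation at the
correlation levels observed in questionnaire data, but stronger dependence,
clustered sampling, or drift in case-mix between stages are outside what
the generator emulates.

## Known limitations

* One classifier only is carried to stage 2; designs validating several
  survivors, data-dependent $n_2$, or more than two stages are out of
  scope.
* Inference is for sensitivity with specificity held fixed by conditioning;
  joint sensitivity–specificity inference is not attempted.
* Combinations of classifiers (model-building on top of the selected item)
  are not covered by the conditional framework implemented here.
* The conditional perspective itself: when the study stops, the package
  deliberately reports nothing about the abandoned candidates.
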