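---
title: "Methods: phenome-wide two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone. For each genetic
instrument $j$ we observe the per-allele association with the exposure,
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$, and with the outcome,
$\hat\beta_{Yj}$ with $\sigma_{Yj}$, estimated in non-overlapping cohorts.
Under the instrumental-variable assumptions (association with the exposure;
independence from confounders; no effect on the outcome except through the
exposure), every valid instrument satisfies
$\beta_{Yj} = \theta\,\beta_{Xj}$, and $\theta$ is the causal effect.

`mrscreen` implements the full screening workflow around this model:
instrument selection, harmonisation, filtering, a battery of estimators with
quality control, composite significance criteria under FDR control,
multivariable MR, and Bayesian model averaging over correlated risk factors.
All of it runs on synthetic summary statistics with known ground truth, so
every stage is testable without external downloads.

## Instrument processing

**Adaptive selection.** Selection starts at genome-wide significance
($p < 5\times10^{-8}$) and relaxes the threshold by a factor of 10 at a time
($5\times10^{-7}$, $5\times10^{-6}$, up to a predefined maximum of
$5\times10^{-5}$) until more than 5 post-clumping instruments are available.
We count instruments *post*-clumping, since only clumped instruments enter
the analysis; traits that cannot reach 6 instruments even at the maximum
threshold are excluded from the screen (flagged, not errored) rather than
analysed underpowered.

**Clumping.** Greedy LD clumping at $r^2 \le 0.001$ within a 10,000 kb
window: the lowest-p remaining candidate becomes an index, correlated
neighbours are discarded, and the process repeats. Variants absent from the
LD reference are treated as independent and reported. The implementation is
tested against a brute-force oracle on random instances.

**Proxies.** An instrument missing from the outcome dataset may be replaced
by the outcome variant in highest LD with it at $r^2 \ge 0.9$, using the
recorded allele phase so the proxy allele that travels with the index
variant's effect allele carries its sign. Proxy associations are attenuated
by the imperfect LD ($\propto r$); this is visible in the simulation tests
and is inherent to proxy substitution, not an implementation artefact.

**Harmonisation.** Outcome betas are expressed per additional copy of the
exposure's effect allele: swapped allele orders flip the sign, strand
complements are re-labelled, and palindromic (A/T, G/C) variants are
resolved by comparing allele frequencies. Palindromic variants with minor
allele frequency above 0.42 in either dataset are dropped — in
effect-allele-frequency terms the ambiguity zone is (0.42, 0.58). We read
"MAF > 0.42" as $\min(\mathrm{EAF}, 1-\mathrm{EAF}) > 0.42$ because MAF is
at most 0.5 by definition. Palindromic variants with missing frequency are
dropped (frequency is the only evidence that can orient them). Palindromic
variants *outside* the ambiguity zone are frequency-aligned rather than
discarded, matching standard harmonisation practice. Every drop is logged
with a reason.

**Filters.** Two orthogonal guards run before estimation (order
configurable; outcome-significance first by default, as the cheaper and more
interpretable filter):

* *Outcome significance*: instruments more significant for the outcome than
  for the exposure ($p_Y < p_X$) are removed — a simple directionality
  heuristic against reverse causation. Note it is only a heuristic: with a
  true causal effect $|\theta| > 1$ and comparable sample sizes valid
  instruments can trip it.
* *Radial outliers*: the radial (Galbraith) IVW fit with modified
  second-order weights — weights $b_{Xj}^2 / (\sigma_{Yj}^2 + \hat\theta^2
  \sigma_{Xj}^2)$ that are iterated with the slope to convergence — yields
  per-variant contributions $q_j$ to Cochran's Q; variants with $q_j$ above
  the $\chi^2_1$ upper 5% point are removed and the fit repeated until no
  outliers remain. The 5% level is applied per variant without multiplicity
  correction (configurable), matching common practice for this filter.

## Estimators

* **IVW** — weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin, weights $1/\sigma_Y^2$. The screen's primary analysis uses
  *multiplicative random effects* (MRE): the fixed-effect standard error is
  inflated by $\max(1, \sqrt{Q/(J-1)})$, so heterogeneity widens intervals
  but cannot narrow them. A phenome-wide screen is certain to include
  heterogeneous instrument sets, which is why MRE, not fixed effects, is the
  default. P-values are normal.
* **MR-Egger** — the same regression with an intercept after orienting all
  instruments to non-negative $\hat\beta_X$; the intercept estimates the
  average directional pleiotropic effect and its test is the pleiotropy
  diagnostic. SEs are inflated by $\max(1, \sqrt{Q_E/(J-2)})$ and p-values
  use $t_{J-2}$. Egger output is reported but never substituted for the
  primary estimate; a significant intercept raises a flag instead.
* **Weighted median** — the inverse-variance-weighted 50th percentile of the
  per-variant Wald ratios, interpolated across cumulative weights; unbiased
  while valid instruments carry at least half the weight.
* **Weighted mode** — the argmax of a weighted kernel density over the Wald
  ratios with a modified-Silverman bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$
  ($\phi = 1$ by default); consistent under the plurality assumption.
* **Radial IVW** — the converged radial fit above, reported alongside.

Ratio-based estimators use first-order ratio SEs ($\sigma_Y/|\hat\beta_X|$)
for their weights — the simplest standard choice. Median and mode SEs come
from a parametric bootstrap (resampling $\hat\beta_X$, $\hat\beta_Y$ from
Gaussians at their SEs; 1000 replicates by default, seed-fixed, so results
are bit-reproducible). The bootstrap count and bandwidth multiplier are
config defaults, not sacred values.

## Quality control

For each analysed pair: mean instrument F-statistic
$\overline{(\hat\beta_X/\sigma_X)^2}$ (flag at $\le 10$); Cochran's Q with
$\chi^2_{J-1}$ p (heterogeneity flag at $p<0.05$); the Egger intercept test
(pleiotropy flag at $p<0.05$); $I^2_{GX}$ — the heterogeneity of the
weighted instrument-strength statistics, $(Q_{GX}-(J-1))/Q_{GX}$ floored at
0, computed from $|\hat\beta_X|$ with weights $1/\sigma_X^2$ — flagging a
NOME violation (Egger biased towards the null) below 0.9; and leave-one-out:
$J$ MRE IVW refits each omitting one instrument, flagged unstable when the
full-set p is significant but any refit p is not. "Nominally significant
throughout the leave-one-out analysis" is read strictly: all $J$ refits must
have $p < 0.05$.

## The screen

Traits are first de-duplicated by normalised name: largest sample size wins,
ties broken by largest mean F-statistic, then lexicographic id. Whole
batches can be excluded (the default excludes `ukb` and `met-d`, the
batches whose cohorts overlap a UK-Biobank-derived outcome). Each surviving
exposure runs the full per-trait pipeline; failures downgrade the trait to
`excluded` with the error recorded rather than aborting the screen.

Benjamini–Hochberg FDR correction is applied across the MRE IVW p-values of
all traits analysed in one screen invocation — the closest reproducible
family to "all traits in the phenome-wide analysis" (the family definition
is configurable). A verdict of `significant` requires all of: FDR-adjusted
IVW $p < 0.05$; weighted-median $p < 0.05$; weighted-mode $p < 0.05$; and
every leave-one-out refit $p < 0.05$.

Continuous exposures are reported as beta and as OR per SD
($e^{\hat\theta}$); binary exposures report beta only, since ORs are not
interpretable per unit of a binary liability.

Replication re-runs the pipeline for significant traits against a second
outcome and stores the results *without* touching primary verdicts: failure
to replicate is not evidence of no effect. `reverse_mr()` swaps the roles of
exposure and outcome to check directionality.

## Multivariable MR

For $K \ge 2$ jointly modelled exposures, the union of per-exposure
instruments (selected at $5\times10^{-8}$, jointly clumped, harmonised to
one allele convention) is regressed:
$\hat\beta_{Yj} = \sum_k \theta_k \hat\beta_{Xjk}$, weights $1/\sigma_Y^2$.
Instrument strength per exposure uses the conditional F-statistic: the
iterated heterogeneity statistic $Q_{Xk}$ of exposure $k$'s betas regressed
on the others (weights propagate the delta coefficients and an assumed
error correlation $\rho$, default 0), divided by $J$ — a form that reduces
exactly to the mean F-statistic at $K=1$. When any conditional F is $\le$ 10
that exposure's threshold relaxes by a factor of 10 (floor $5\times10^{-5}$,
mirroring the univariable ladder); if the floor is reached the set is
returned flagged weak.

The adjusted Cochran's Q propagates exposure measurement error:
$Q_A(\theta) = \sum_j (\hat\beta_{Yj}-\theta^\top\hat\beta_{Xj})^2 /
(\sigma_{Yj}^2 + \sum_k \theta_k^2\sigma_{Xjk}^2 +
2\sum_{k<l}\theta_k\theta_l\,\rho\,\sigma_{Xjk}\sigma_{Xjl})$, with $J-K$
degrees of freedom. When it signals heterogeneity, `qmin_estimate()`
minimises $Q_A$ over $\theta$ (BFGS from the IVW solution; the minimiser can
never be worse than its start, which is tested). $\rho$ is set by
assumption, not estimated — analyses are typically run at both $\rho = 0.1$
and $\rho = 0.9$ and conclusions checked for stability. Confidence intervals
come from inverting the per-component profile of $Q_A$ at the $\chi^2_1$
95% cut-off — a deterministic choice (no bootstrap) that makes the intervals
exactly reproducible and testable.

## MR-BMA

For many correlated candidate risk factors, Bayesian model averaging scores
subsets $S$ of traits on the standardised design $y_j =
\hat\beta_{Yj}/\sigma_{Yj}$, $x_{jk} = \hat\beta_{Xjk}/\sigma_{Yj}$
(columns scaled to unit variance so shrinkage acts evenly). Each model is a
conjugate Gaussian linear model — effect prior $N(0, \sigma_p^2 I)$ with
$\sigma_p^2 = 0.25$ treated as a *variance*, unit residual variance, model
prior $p^{|S|}(1-p)^{K-|S|}$ with $p = 0.1$ — so the marginal likelihood is
closed-form. A stochastic shotgun search (10,000 add/delete/swap Metropolis
iterations by default) caches every distinct model it scores and normalises
posterior mass over the cache; for $K \le 12$ an exhaustive enumeration mode
exists and the search is required (and tested) to agree with it to within
0.01 per-trait MIP. The marginal inclusion probability (MIP) of a trait is
the summed posterior probability of models containing it; the model-averaged
causal estimate (MACE) weights each model's shrinkage estimate by its
posterior probability, counting 0 when the trait is absent — a conservative,
standardised-scale quantity indicating direction more than magnitude.

Traits with pairwise instrument-beta correlation $\ge 0.99$ cannot be
separated by any multivariable method; one of each such pair is removed at
random (seeded) rather than by hand, avoiding selection bias. Influential
instruments are diagnosed per top model via Cook's distance from the
least-squares fit (flagged above the median of an $F_{|S|, J-|S|}$
reference) and the per-variant heterogeneity contribution
$q_j = (y_j - x_j^\top\hat\theta_S)^2$ (flagged above the $\chi^2_1$ upper
$0.05/J$ point). Flagged variants are removed and the whole analysis
re-run until clean; if removal would leave fewer instruments than model
parameters the analysis aborts as degenerate. The outlier cut-offs are our
own choices (exposed in the interface), since only statistic ranges, not
thresholds, are standard for these diagnostics.

Per-trait empirical p-values permute the standardised response $y$ while
keeping the design fixed — preserving the predictor correlation structure
under the null — and report the proportion of permutations whose MIP
reaches the observed one (with the usual +1 correction so p > 0). The
default is 100,000 permutations; test-scale analyses use 1,000 or fewer.
For $K \le 12$ permutations are scored by exhaustive enumeration (exact and
fast, vectorised across permutations); for larger panels each permutation
re-runs the stochastic search. Both modes are provided because either is a
defensible reading of "permutation re-analysis"; they agree in the regime
where both run. Benjamini–Hochberg FDR is applied across traits.

## The synthetic-data generator

`simulate_pair()` and `simulate_multi_exposure()` generate GWAS summary
statistics with known truth. True exposure effects are zero-centred Gaussian
(SD 0.05 by default); with the default cohort size of 50,000 the per-variant
F-statistics span tens to hundreds, exercising the mean-F gate on both
sides. Observed estimates add Gaussian noise at
$\sigma = (2n\,\mathrm{EAF}(1-\mathrm{EAF}))^{-1/2}$, the standard error of
a standardised per-allele regression; p-values use the normal
approximation, matching how selection thresholds are applied.

Key generative choices:

* **Directional pleiotropy is expressed per exposure-increasing allele**
  ($\alpha_j = \mathrm{sign}(\beta_{Xj})\cdot N(\mu_\alpha,
  \sigma_\alpha)$). Allele labels are arbitrary, so a direction can only be
  defined relative to an orientation; this is the orientation MR-Egger
  estimates, and it is what makes "mean pleiotropy $\mu_\alpha$" a
  recoverable quantity. Balanced pleiotropy is orientation-free
  ($N(0,\sigma_\alpha)$); correlated pleiotropy runs through a latent
  confounder with loadings on exposure and outcome, which is also how the
  mediation/correlated-pleiotropy MVMR scenario is constructed.
* **Reverse-causal variants** have a direct outcome effect and an induced
  exposure association at a configurable fraction of it, giving the
  outcome-significance filter true positives to find.
* **LD** is block-diagonal with a per-variant haplotype orientation, so
  pairwise allele phase is transitively consistent within a block, and true
  effects of block members are correlated at $\sqrt{r^2}$ with
  phase-consistent signs — enough structure for clumping and proxy
  substitution to be meaningfully testable. It is *not* a realistic human
  LD map: pairwise $r^2$ values within a block are drawn independently
  rather than from a consistent correlation matrix, and observed noise is
  independent across variants. Tests passing here do not certify behaviour
  on real panel LD.
* **Encodings**: configurable fractions of variants are palindromic (with
  frequencies in or out of the ambiguity zone), listed with swapped alleles
  in the outcome (beta negated — a pure re-encoding), strand-flipped, or
  missing from the outcome entirely.

Seeded runs are byte-reproducible; the generator never reads anything
external.

## Problem sizes and numerical choices

The test-suite and acceptance-script scenarios use 40–80 variants per trait,
20-trait screens, $K \le 10$ exposure panels, 200–1000 replicates for
calibration quantities and 1000 permutations for MR-BMA p-values — sizes
chosen so each property is measured with useful Monte-Carlo precision while
a full run stays comfortable on one CPU. The weighted-median robustness
scenario uses larger cohorts (n = 500,000) and stronger effects (SD 0.2)
than the other calibration scenarios: the weighted median's finite-sample
bias under one-sided contamination scales with the ratio-noise of valid
instruments, so a biobank-scale design is the regime where its robustness
guarantee is the property actually on display. Estimator-calibration
scenarios apply genome-wide instrument selection before fitting, as the
pipeline does; feeding near-null variants to MR-Egger mis-orients a
fraction of them and dilutes the intercept, which is a property of the
orientation convention, not of the estimator.

Numerical details worth knowing: radial weights iterate to $|\Delta\theta| <
10^{-10}$; weighted-median interpolation is linear in cumulative weight;
the mode's bandwidth falls back to the heaviest point mass when the ratio
spread is degenerate (MAD 0); Q-minimisation uses BFGS with profile-CI
brackets expanded geometrically before root-finding; BMA model scoring uses
Cholesky solves of $X_S^\top X_S + I/\sigma_p^2$ (never explicit
inverses), and ties in greedy clumping break by variant id so output is
deterministic.

## Known limitations

* The generator's LD is stylised (see above); clumping and proxy logic are
  exercised, but population-realistic LD behaviour is untested.
* The outcome-significance filter misbehaves for causal effects $|\theta| >
  1$; the screen does not guard against that regime.
* MACE is a standardised-scale, shrinkage-averaged quantity — a ranking
  aid, not an effect size for downstream use.
* Binary-trait effects are treated on the log-odds scale throughout; no
  case-control ascertainment or winner's-curse modelling.
* The FDR family is per screen invocation; combining screens across
  invocations requires re-adjustment by the caller.
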