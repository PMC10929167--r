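---
title: "Methods: two-sample MR screening from GWAS summary statistics"
author: "mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrscreen)
```

## The inference problem

`mrscreen` estimates causal effects of many exposures (the motivating
application is relative abundances of gut-microbial taxa) on a single
outcome (a time-to-event phenotype for immunotherapy toxicity) using
nothing but GWAS summary statistics from two non-overlapping samples.
For each instrument $j$ we observe the per-allele association with the
exposure, $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$, and with the
outcome, $\hat\beta_{Yj} \sim N(\theta\gamma_j + r_j, \sigma_{Yj}^2)$,
where $\theta$ is the causal effect of interest and $r_j$ is a
horizontal-pleiotropy term, zero for a valid instrument. On the outcome
side a *negative* beta means a shorter time to the adverse event, i.e.
higher risk, so negative $\theta$ identifies risk-increasing taxa.

The three instrumental-variable assumptions (relevance, independence
from confounders, exclusion restriction) motivate the design of every
module: instrument selection enforces relevance, the
confounder-annotation join supports the independence check, and the
pleiotropy-robust estimators and diagnostics interrogate the exclusion
restriction.

## Instrument selection

Four screens, in order, with defaults matching the conventions of
microbiome-GWAS MR:

* association p-value $< 10^{-5}$ (strict inequality; microbial taxa
  rarely reach genome-wide significance, so the conventional relaxed
  threshold is the default);
* greedy LD clumping at $r^2 \ge 0.001$ within a two-sided 10 Mb
  window, best p-value first, ties broken lexicographically by variant
  id (the de-facto PLINK rule; the clumping reference is supplied as a
  precomputed pairwise $r^2$ table, never derived from genotypes here,
  and absent pairs count as independent);
* per-instrument strength $F = (\hat\beta/\mathrm{se})^2 > 10$;
* at least 3 surviving instruments per exposure, otherwise the exposure
  is dropped with a logged reason.

The $F$ screen is applied *after* harmonization so that the instruments
reported are exactly the instruments analyzed.

## Harmonization

Instruments are matched to the outcome table by variant id. When the
outcome lists the alleles in swapped order the outcome beta is negated
and the effect-allele frequency complemented. Palindromic (A/T, C/G)
variants are removed by default because their strand cannot be resolved
from alleles alone; an optional frequency-based rescue (both EAFs
outside 0.42–0.58) exists but is off by default, which is the more
conservative reading of standard practice. Instruments absent from the
outcome may be replaced through a user-supplied proxy table at
$r^2 > 0.8$; there are no network lookups, so a run is fully
reproducible from its inputs. Every input instrument receives exactly
one audit disposition (`kept`, `sign_flipped`, `proxied`,
`removed_palindromic`, `removed_mismatch`,
`removed_missing_in_outcome`), making the audit a conservation law that
the test suite checks property-style.

## Estimators

All estimators act on the harmonized vectors; $w_j = 1/\sigma_{Yj}^2$.

* **Wald ratio** (single instrument): $\hat\beta_{Yj}/\hat\beta_{Xj}$,
  first-order delta-method SE $\sigma_{Yj}/|\hat\beta_{Xj}|$.
* **IVW**: weighted LS of outcome on exposure effects through the
  origin. The fixed-effect SE is $(\sum_j w_j\hat\beta_{Xj}^2)^{-1/2}$;
  the default mode inflates it by $\sqrt{Q/(J-1)}$ when that factor
  exceeds one (multiplicative random effects, never deflating). Both
  modes are available because the source analyses do not state which
  was used per taxon.
* **Maximum likelihood**: joint normal likelihood over
  $(\theta, \gamma_1..\gamma_J)$, so exposure-side measurement error is
  modelled; BFGS with analytic gradient from the IVW start, SE from the
  observed information. When $\sigma_{Xj} \to 0$ it reduces to
  fixed-effect IVW, which the tests assert.
* **MR-Egger**: instruments re-oriented so $\hat\beta_{Xj} \ge 0$
  (without which the intercept is uninterpretable), then weighted LS
  *with* intercept. A nonzero intercept estimates directional
  pleiotropy. SEs use the no-underdispersion convention (residual scale
  floored at 1); p-values from $t_{J-2}$.
* **Weighted median**: ratio estimates ordered, weights
  $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ normalized, linear interpolation of
  the standardized cumulative weight $(S_j - w_j/2)/S_J$ at one half.
  Consistent while valid instruments carry over half the weight.
* **Weighted mode**: Gaussian-kernel weighted density of the ratios,
  bandwidth $\varphi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{IQR}/1.34)\,J^{-1/5}$ with $\varphi = 1$ by default,
  512-point grid spanning the ratios $\pm 3$ bandwidths; the estimate
  is the density argmax. If all ratios coincide the common ratio is
  returned. The estimate is stable under bandwidth doubling only when
  clusters are separated by several bandwidths; with closely spaced
  clusters the Silverman-type rule is wide and the argmax can move,
  which is inherent to the method, not a numerical artifact.

Median and mode SEs come from a seeded parametric bootstrap (both
effect vectors redrawn from their sampling normals; 1000 replicates by
default, minimum 100). All estimator randomness flows from one explicit
seed in `mr_config()`, and bit-reproducibility under a fixed seed is
asserted in the tests. P-values are normal-based except MR-Egger's
($t_{J-2}$).

## MR-PRESSO

The global test simulates the null distribution of the weighted
residual sum of squares around leave-one-out IVW fits; the p-value is
$(1 + \#\{\mathrm{RSS}^\ast \ge \mathrm{RSS}\})/(n_{\mathrm{sim}}+1)$,
floored at $1/(n_{\mathrm{sim}}+1)$ so zero is never reported. Each
instrument's observed residual is compared to its own simulated
distribution; because residuals enter squared, the upper tail captures
deviations of both signs. Outlier flags are Bonferroni-corrected over
$J$, so resolving an outlier at $\alpha = 0.05$ with $J \approx 20$
needs $n_{\mathrm{sim}} > 420$; the suite uses 600 where it plants
outliers and the default is 1000. The distortion test compares the
before/after estimate change against removals of random subsets in the
simulated nulls. The outlier-corrected IVW is reported separately and
never silently replaces the headline estimate. The test is undefined
below 4 instruments, where the screening gate falls back to IVW alone.

## cML-MA-BIC

The pleiotropy-extended likelihood constrains at most $K$ of the $r_j$
to be nonzero. For fixed $K$ the fit alternates (i) selecting the $K$
instruments with the largest standardized outcome residuals as invalid
and (ii) re-estimating $\theta$ on the valid set by exact 1-D
minimization of the profile likelihood ($\gamma$ profiled out in closed
form). Model averaging across $K = 0..J-2$ uses
$\mathrm{BIC}_K = 2\,\mathrm{NLL}_K + K\log n_{\mathrm{eff}}$, weights
$\propto e^{-\Delta\mathrm{BIC}/2}$, and the standard model-averaging
variance $\sum_K w_K(\mathrm{se}_K^2 + (\theta_K - \theta_{MA})^2)$.
$n_{\mathrm{eff}}$ defaults to the smaller of the two GWAS sample
sizes, which is the natural BIC sample size when none is stated.

Three numerical choices matter and are deliberate:

* the profile likelihood has a degenerate ridge — as
  $|\theta| \to \infty$ with $\gamma_j \to 0$ the NLL approaches the
  finite constant $\sum_j F_j/2$ — which becomes the *global* optimum
  of the under-constrained ($K$ too small) problem whenever large
  unfitted pleiotropy is present. The 1-D step therefore scans a grid
  before golden-section refinement, and the random restarts are diverse
  causal-effect hypotheses (the IVW estimate, zero, and randomly drawn
  single-instrument Wald ratios) that seed the *support selection*
  first; as long as a majority of instruments is valid, at least one
  start tracks them;
* a support 2-cycle in the discrete selection is resolved by exactly
  refitting each member of the cycle and keeping the best likelihood —
  the iteration is a heuristic for a combinatorial search, and the best
  cycle member is its answer;
* after the support stabilizes, $\theta$ is polished to near machine
  precision by closed-form alternation, so the $K=0$ fit agrees with
  the unconstrained ML fit to at least six decimals (asserted).

The suite verifies that the estimator holds its nominal 5% size with no
pleiotropy and also under 30% *directional* pleiotropy when the
pleiotropic effects are large enough to identify (tens of outcome SEs).
In the marginal regime — planted effects comparable to the outcome SE,
which the generator's default half-normal scale produces — the point
estimate remains unbiased but the model-averaged SE understates the
selection-induced spread and the size inflates moderately. This is a
known finite-sample property of BIC model averaging without data
perturbation; the data-perturbation variant that repairs it is out of
scope here, and the behaviour is left visible in the acceptance suite
rather than masked.

## Diagnostics

Cochran's $Q$ uses the fixed-effect IVW centre regardless of the
reporting mode (the standard definition), with the upper
$\chi^2_{J-1}$ tail. Leave-one-out re-runs IVW dropping each instrument
in turn. Confounder screening is a pure left join of instruments
against a user-supplied SNP-trait table (an offline export of a
phenotype-annotation service); flagged instruments are surfaced for
review, never auto-excluded, and the leave-one-out table already shows
the effect of removing any one of them — mirroring how such checks are
reported in practice.

## Multivariable MR

Instruments are the union of the per-exposure selections, clumped
jointly with each variant scored by its best p-value across exposures,
and every retained instrument must carry an allele-aligned effect for
every exposure and the outcome. The fit is weighted LS of the outcome
effects on the instrument-by-exposure matrix without intercept
(fixed-effect weights $1/\sigma_{Yj}^2$); rank deficiency raises an
error naming the collinear exposures. Residual heterogeneity is
summarized by the weighted RSS ($\chi^2_{J-k}$), and a per-exposure
conditional instrument-strength statistic (mean weighted squared
residual of that exposure's effects regressed on the others') is
reported as a diagnostic only. With one exposure the fit reduces
exactly to fixed-effect IVW, which is asserted.

## The screening pipeline

Per exposure: selection, clumping, harmonization, strength filtering,
the estimator battery, diagnostics, MR-PRESSO ($J \ge 4$) and
cML-MA-BIC. The suggestive gate requires both the IVW p-value and the
MR-PRESSO causal-estimate p-value (outlier-corrected when outliers were
found) below $\alpha = 0.05$; this reading of the dual gate — rather
than gating on the PRESSO *global heterogeneity* p — is the one under
which a null screen flags about 5% of taxa, which the calibration test
verifies. The Bonferroni threshold is always computed as $\alpha/m$
from the number of exposures actually analyzed (for the motivating
study's 132 taxa that is $0.05/132 = 3.79\times10^{-4}$); it is never
hard-coded. Reverse MR swaps the roles and reuses the identical
machinery. Per-pair seeds are derived from the master seed and the
exposure *name*, so the screen is exposure-order invariant, another
asserted property. Every reported number is recomputable from the
stored harmonized sets plus the recorded seeds.

## The synthetic generator

`sim_config()` defaults encode the study conditions the package
targets: an 18,340-participant exposure consortium against a
1,751-patient outcome cohort; 7 instruments per taxon (the motivating
screen retained 870 SNPs across 132 taxa); per-instrument true $F$
drawn uniformly on (17, 37), spanning the reported instrument-strength
range 16.91–36.57; MAF uniform on (0.05, 0.5) with the
standardized-trait SE approximation
$\mathrm{se} = (2p(1-p)n)^{-1/2}$; instrument effects
$\gamma_j = \pm\sqrt{F}\,\mathrm{se}_X$ so instruments clear the
$10^{-5}$ screen at their nominal strength. Pleiotropy is balanced
(zero-mean normal), directional (half-normal, one-signed) or correlated
($r_j \propto \gamma_j$ plus noise, violating the
instrument-strength-independent-of-direct-effect assumption on
purpose, which is what exercises cML's headline robustness). LD blocks
place within-block pairs at a configurable $r^2$ and blocks more than a
window apart; palindromic and allele-swapped fractions exist solely to
exercise harmonization. One master seed is split deterministically per
taxon, so datasets are byte-identical under a fixed seed.

What the generator does *not* emulate: compositional covariance between
taxa, realistic LD decay, population stratification, or sample overlap
between the two GWAS. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
those real-data complications.

## Problem sizes and validation regimes

The validation studies run at desk scale, sized to keep the full suite
within minutes while leaving Monte-Carlo error well below the margins
being asserted: 2000 replicates for the IVW type-I study, 500 for the
cML size study (15 instruments), 100 planted-outlier replicates with
600 PRESSO simulations, 100 null panels of 132 taxa for screen
calibration, and 200 replicates per truth value for estimator recovery.

Two regime choices deserve emphasis. First, the recovery study runs
with consortium-precision exposure effects (effective per-instrument
$F \sim 10^3$–$10^4$): all ratio-based estimators (IVW, Egger, median,
mode) carry a regression-dilution attenuation of order $\theta/(F+1)$,
so at the realistic $F \approx 17$–$37$ a mean-recovery assertion
within Monte-Carlo error would test the attenuation, not the
implementation. The attenuation itself is verified separately at the
realistic strength (the generator consistency test expects IVW within
$\pm 0.05$ of $\theta = -1$, consistent with the predicted
$\approx 3.7\%$ shrinkage), and the maximum-likelihood estimator, which
models exposure noise, does not share it. Second, the type-I assertion
is made on the fixed-effect IVW test, for which the nominal level is
exact; the default multiplicative random-effects mode is deliberately
conservative (it can only widen intervals).

## Known limitations

* No strand inference from a reference genome: palindromic handling is
  removal (or optional EAF rescue), never sequence-based resolution.
* LD is consumed, not computed; a missing pair is assumed independent.
* The cML data-perturbation variant is not implemented; see above for
  the size consequences in the marginal-pleiotropy regime.
* MVMR is fixed-effect IVW only (no MVMR-Egger or median).
* The distortion test reports but does not act; analysts choose between
  raw and outlier-corrected estimates.
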