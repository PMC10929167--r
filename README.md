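# mrscreen

Two-sample Mendelian randomization (MR) screening of many exposures
against a GWAS outcome, from summary statistics alone.

The package was built for microbiome-to-disease screens: host genetic
variants associated with the relative abundance of gut-microbial taxa
(mbQTLs) serve as instrumental variables, and their effects on an
immunotherapy-toxicity phenotype — a time-to-event trait where a
*negative* variant effect means a shorter time to the adverse event,
i.e. higher risk — are combined into causal-effect estimates. Nothing
is microbiome-specific, however: any collection of exposure GWAS
tables plus one outcome GWAS table fits the interface.

## The model

For instrument $j$, with $\hat\beta_{Xj} \sim N(\gamma_j,\sigma_{Xj}^2)$
its observed effect on the exposure and
$\hat\beta_{Yj} \sim N(\theta\gamma_j + r_j,\sigma_{Yj}^2)$ its
observed effect on the outcome, the causal effect $\theta$ is estimated
by seven complementary methods: the Wald ratio, inverse-variance
weighting (IVW, fixed or multiplicative random effects), maximum
likelihood, MR-Egger regression (slope plus a directional-pleiotropy
intercept test), the weighted median, the weighted mode, and
constrained maximum likelihood with BIC model averaging (cML-MA-BIC),
which selects the set of invalid instruments ($r_j \ne 0$) by
likelihood and is robust to both uncorrelated and correlated
pleiotropy. MR-PRESSO detects outlier instruments by simulating the
null of the leave-one-out residual sum of squares. Cochran's Q,
leave-one-out re-estimation and an offline SNP–trait annotation join
provide diagnostics; multivariable MR (weighted multiple regression of
outcome effects on several exposures' effect columns) estimates direct
effects conditional on covariable exposures such as BMI.

Instrument processing follows standard summary-statistics practice:
p < 1e-5 screen, greedy LD clumping (r² 0.001, 10 Mb window, best-p
first), allele harmonization with sign-flips for swapped codings,
removal of palindromic variants, optional LD-proxy substitution
(r² > 0.8), per-instrument F = (β/se)² > 10, and at least three valid
instruments per exposure. A forward screen runs the whole battery per
exposure and flags pairs with both IVW and MR-PRESSO p-values below
0.05 as suggestive, and IVW p below 0.05/m (m = exposures analyzed) as
Bonferroni-significant; reverse MR swaps the roles.

A synthetic summary-statistic generator (`sim_config()`,
`simulate_mr_pair()`, `make_null_panel()`) produces paired
exposure/outcome tables with known causal effects, pleiotropy of
configurable type, LD blocks, and deliberately corrupted allele
codings, so the entire chain is testable without any data download.

## Worked example

Simulate three taxa — one causal at θ = −2 (negative on this
time-to-event scale: the taxon shortens the time to toxicity, i.e.
increases risk), two null — and screen them:

```r
library(mrscreen)

sim <- simulate_mr_pair(sim_config(n_taxa = 3, theta = c(-2, 0, 0),
                                   instruments_per_taxon = 8, seed = 42))
scr <- run_forward_screen(sim$exposures, sim$outcome, sim$ld,
                          screen_config(presso_n_sim = 200, n_boot = 200,
                                        seed = 7))
scr
#> MR forward screen: 3 pair(s) analyzed, 0 dropped
#>   suggestive (dual gate, alpha = 0.05): 1
#>   Bonferroni (p < 0.0167 = alpha/3): 1

scr$flags[, c("exposure", "nsnp", "ivw_p", "suggestive", "bonferroni")]
#>    exposure nsnp        ivw_p suggestive bonferroni
#> 1 taxon_001    6 1.446588e-08       TRUE       TRUE
#> 2 taxon_002    7 7.038772e-01      FALSE      FALSE
#> 3 taxon_003    7 7.605964e-01      FALSE      FALSE
```

Only the causal taxon survives the Bonferroni threshold, which the
screen computed as 0.05/3 from the number of exposures analyzed. The
full estimator battery for that pair:

```r
fit <- mr_fit(scr$harmonized[["taxon_001"]],
              config = mr_config(n_boot = 200, seed = 7))
summary(fit)
#> Two-sample MR fit: taxon_001 -> outcome (6 instruments)
#>              method nsnp   beta     se ci_low ci_high      pval
#>                 ivw    6 -2.081 0.3672 -2.801  -1.361 1.447e-08
#>  maximum_likelihood    6 -2.179 0.2746 -2.717  -1.641 2.114e-15
#>               egger    6  1.022 1.2535 -2.458   4.502 4.607e-01
#>     weighted_median    6 -2.226 0.4204 -3.050  -1.402 1.192e-07
#>       weighted_mode    6 -2.387 0.5936 -3.550  -1.224 5.791e-05
#> Cochran's Q = 13.6 on 5 df (p = 0.0184)
#> Egger intercept = -0.2355 (se 0.09314, p = 0.0648)
```

IVW, ML, weighted median and weighted mode all recover β near the true
−2 (a risk-increasing effect on this time-to-event scale). MR-Egger is
characteristically uninformative at six instruments — its slope CI
spans everything — which is why it serves as a pleiotropy diagnostic
here rather than a primary estimator. `plot(fit)` draws the
instrument-level scatter with the fitted slopes, `leave_one_out(...)`
and `run_presso(...)` probe single-instrument influence, and
`write_screen(scr, dir)` emits tidy TSV tables plus a JSON manifest
with every threshold and seed needed to reproduce the run.

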