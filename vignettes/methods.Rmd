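---
title: "Models and methods behind biofortqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind biofortqg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`biofortqg` analyses multi-environment evaluations of cassava germplasm
grown in augmented block designs, with a focus on biofortification
targets: total carotenoid content (TCC), root dry matter, yields,
harvest index, starch, pulp colour and cyanogenic compounds. This
vignette explains the models, the tunable parameters and the numerical
choices, and states what the synthetic-data machinery does and does not
demonstrate about real field data.

## The mixed model

Each trait is analysed separately with the linear mixed model

$$Y_{ijk} = \mu + E_i + B_{(i)j} + G_k + GE_{ik} + \varepsilon_{ijk},$$

where $E_i$ is the random effect of trial (environment) $i$, $B_{(i)j}$
the random block-within-trial effect, $GE_{ik}$ the random
genotype-by-trial interaction and $\varepsilon_{ijk}$ the residual, all
taken as independent Gaussians. The genotype effect splits as
$G_k = T_{k'} + T_{(j)k}$: the replicated common checks $T_{k'}$ are
fixed effects (treatment contrasts against the test-clone baseline, so
the fitted intercept estimates $\mu$), while the unreplicated test
clones $T_{(j)k}$ are random, which is what makes prediction possible
in an augmented design — the checks calibrate block and trial effects,
and the clone effects borrow strength through shrinkage.

`fit_trait_blup()` estimates the variance components by REML (through
`lme4`, with the test-clone term entered as a random slope on a 0/1
test indicator so that check plots contribute exactly nothing to it)
and reports each clone's BLUP and BLUP-plus-intercept, the scale on
which genotype means are compared and selected. Reported BLUPs add the
intercept $\hat\mu$ alone by default; `intercept =
"mu_plus_mean_check"` also adds the mean check effect, since the
"overall mean" of an augmented trial is ambiguous between the two
conventions.

Numerical choices: variance components are constrained non-negative by
the profiled-REML parameterisation; optimizer tolerances are tightened
(`xtol_abs = 1e-10`, `ftol_abs = 1e-12`) so that balanced designs
reproduce closed-form ANOVA estimators to better than $10^{-6}$; a
component estimated exactly at zero is a valid boundary optimum, not a
convergence failure. Random terms that the data cannot identify are
dropped with a warning: the trial term needs two trials, the
block term more blocks than trials, the interaction at least one
genotype observed in two or more trials.

Significance of each random term is assessed by the likelihood-ratio
deviance test, $\chi^2 = 2(\ell_{full} - \ell_{reduced})$ on one degree
of freedom at the 1 % level (`lrt_term()`). Because the null value of a
variance component sits on the boundary of its parameter space, the
plain $\chi^2_1$ reference is conservative — the realised null
rejection rate falls at or below the nominal level — and no 50:50
mixture correction is applied, matching common practice in germplasm
evaluation reports.

## Heritability and genetic gain

Broad-sense heritability on the plot level and on the clonal-mean
level:

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge} + \sigma^2_e},
\qquad
h^2_m = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e +
\sigma^2_e/(re)},$$

with $e$ the number of trials carrying the trait and $r$ the effective
replication. Field definitions of $r$ vary; the package computes the
harmonic mean of each test clone's plot count across the included
trials, divided by $e$ (so an unreplicated clone evaluated once per
trial gives $r = 1$), and both $e$ and $r$ can be overridden in
`heritability()`.

Predicted gain from selecting a parent set is $G = h^2_m S$, where the
selection differential $S$ is the deviation of the selected clones'
mean BLUP-plus-intercept from the population mean; the percent gain
divides by the population mean. Published tables of this kind do not
always back-calculate exactly from their printed means under either
$h^2_m S$ or $h^2 S$ (undisclosed rounding in intermediate steps is the
likely cause), so `gain_report()` reports internally consistent values
computed from its own inputs rather than attempting to reproduce any
particular printed percentage.

## Selection index

`compute_index()` implements the weighted-BLUP index
$SI_g = \sum_t w_t\, b_{gt}$ with default economic weights
(carotenoids and pulp colour 30, fresh/dry yield and root number 10,
dry matter, shoot yield, harvest index and starch 5, cyanogenic score
−30). Because a raw weighted sum is unit-dependent, a per-trait
z-scoring flag and a rank-summation mode (Mulamba–Mock style, weights
applied to within-trait ranks) are provided; the weighted-BLUP form is
the default because it is the explicitly defined formula. Genotypes
missing any weighted trait are excluded with a warning rather than
imputed: index values over unequal trait sets are not comparable.
Top-$n$ selection (default $n = 30$) breaks ties lexicographically by
genotype id, logged when it happens.

## Correlation and network analysis

Trait relationships are computed on the genotype-level
BLUP-plus-intercept table, not on raw plots, so that they reflect
genetic signal rather than plot noise. `pearson_matrix()` uses
pairwise-complete observations (carotenoids exist only for a genotype
subset), with two-sided p from the $t$ statistic on $n-2$ degrees of
freedom and no multiple-testing correction by default.
`order_correlogram()` orders traits by average-linkage clustering on
$1 - r$.

`partial_correlation_network()` estimates a sparse Gaussian graphical
model: the standardised traits' correlation matrix enters a graphical
lasso (block coordinate descent with a coordinate-descent lasso inner
loop, written in the package), the penalty is chosen from 50
log-spaced values spanning three decades below the largest absolute
correlation, and model selection uses the extended BIC with
$\gamma = 0.5$. One deliberate refinement: each candidate support is
scored at its *constrained maximum likelihood* (classical covariance
selection, `ggm_constrained_mle()`) rather than at the penalised
estimate. Scoring the penalised estimate lets the shrinkage bias on
strong edges dominate the criterion, which drags the selected penalty
toward zero and keeps spurious edges; with refit scoring, a 3-variable
chain $X - Y - Z$ drops the conditionally absent $X$–$Z$ edge in
roughly 95 % of simulated datasets at $n = 500$, and 12-trait chain
structures are recovered with essentially perfect recall and no false
edges at that sample size.

## Diversity clustering

`pca_scores()` z-scores the traits (their units are incommensurable),
mean-imputes missing cells per trait (logged), and fixes component
signs by the largest-loading-positive rule so results are fully
deterministic. `kmeans_bic_scan()` runs K-means for $k = 2\dots15$
(25 restarts each, seeded) and scores each solution by the
parameter-counting BIC

$$BIC(k) = n \ln(WSS_k/n) + k\,p \ln n,$$

charging each fitted centre its $p$ coordinates (the X-means
convention). The often-quoted one-parameter-per-cluster form
$n\ln(WSS/n) + k\ln n$ was tried first and systematically over-split
Gaussian groups at every geometry examined — even two well-separated
blobs were split into 7–8 groups — because the within-sum reduction
from one extra adaptive centre grows with $n$ while that penalty grows
only like $\ln n$. The BIC is isolated in one expression and easy to
substitute. Ties select the smaller $k$. `summarize_clusters()` adds
per-cluster descriptive statistics and all pairwise Welch comparisons
per trait with step-down Holm adjustment (stars at 0.05/0.01/0.001);
clusters smaller than two members are excluded from testing.

## The synthetic-trial generator

`simulate_trials()` draws data from exactly the mixed model above:
checks appear in every block, each test clone once per trial in a
random block — the repeated-evaluation structure of a germplasm
collection, which keeps $\sigma^2_{ge}$ estimable. Genotype effects are
drawn across traits from a zero-mean multivariate normal with
covariance $D R D$ ($D$ the genetic standard deviations, $R$ a
configurable correlation matrix); trial, block, interaction and error
effects are independent Gaussians per trait.

Defaults are the package's reference conditions: 265 test clones, 10
checks, 21 trials with 5–22 blocks, trait means and
genotype/interaction/error components from `reference_components()`
(e.g. TCC: $\sigma^2_g = 5.44$, $\sigma^2_{ge} = 0$,
$\sigma^2_e = 2.16$, mean 4.09 µg g⁻¹), carotenoids measured in only
the last two trials, and a signed genetic-correlation structure with a
strong TCC–pulp-colour link (0.70) and a near-zero TCC–dry-matter
link. Trial- and block-level variances have no published reference
values; they are set relative to the error variance
($\sigma^2_{env} = 2\sigma^2_e$, $\sigma^2_{block} = 0.25\sigma^2_e$)
as a plausible field-trial magnitude, and are estimated but reported
separately from the heritability components. Percent-scale traits are
truncated into $[0,100]$ and root counts at zero, since the Gaussian
model is unbounded; ordinal traits (pulp colour 1–3, cyanogenic score
1–9) are generated on the latent continuous scale on which the linear
model operates, with optional thresholding (`discretize_scores`).

`backfill_raw_measurements()` inverts the trait-derivation formulas
(weights in air/water from gravimetric dry matter, absorbance from
carotenoid content, plot weights from per-hectare yields, and so on) so
the raw-measurement path can be exercised end to end; composite traits
(harvest index, dry yield) are recomputed from the back-filled inputs
so the dataset stays internally consistent, and root counts are kept
fractional to preserve exact inversion. Gravimetric dry matter below
16.3 % is not representable with a non-negative underwater weight and
is rejected.

What passing simulation tests shows — and does not. The generator
matches the model the estimator assumes, so parameter-recovery tests
validate the estimation machinery, not the model's adequacy for real
cassava trials: there is no spatial field trend, no genotype-by-year
autocorrelation, no non-Gaussian error, and no unbalanced missingness
beyond the trait-by-trial map. Real-data features like assay error in
the gravimetric regression (values outside $[0,100]$ are flagged, not
clamped) are deliberately surfaced rather than modelled away.

## Problem sizes used in validation

The shipped tests and the acceptance script use moderate, fixed
problem sizes chosen as realistic desk-scale study conditions: REML
recovery at 300 clones × 6 trials over 20 seeds; null calibration of
the deviance test over 1000 single-trial replicates (30 clones, 4
blocks); network recovery at 12 traits × 500 genotypes over 10 seeds;
cluster recovery at 6 groups × 20 genotypes in 11-trait space over 10
seeds. All randomness flows from a single integer seed.

## Known limitations

Traits are fitted independently (no multi-trait REML); residual
variances are homogeneous across trials; the effective-replication
convention affects $h^2_m$ and hence predicted gains; the network's
penalty-selection defaults are a convention, not a published setting;
and printed gain percentages from comparable published tables cannot be
reproduced exactly for the reasons given above.
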