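---
title: "A twin-family model of direct genetic transmission and genetic nurture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A twin-family model of direct genetic transmission and genetic nurture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgstransmit)
```

## The scientific question

A child can resemble their parents genetically through two distinct
channels. *Direct genetic transmission* is the effect of the alleles the
child actually inherits: each parent passes exactly half of their autosomal
DNA, and the transmitted variants act in the child's own body. *Genetic
nurture* is subtler: parental genotype shapes the rearing environment —
parenting style, household resources, cognitive stimulation — and that
environment in turn affects the child, so even *non-transmitted* parental
alleles can leave a mark on the child's phenotype. Separating the two
matters because genetic nurture is, in principle, amenable to environmental
intervention while direct transmission is not.

With polygenic scores (PGS) measured on both parents and children, the two
channels leave different statistical fingerprints: direct transmission acts
through the child's own PGS, nurture shows as a residual contribution of
the parental PGS once the child's PGS is controlled. `pgstransmit`
implements a two-group structural equation model that estimates both
channels from *twin-family* data (mother, father and a twin pair per
family), which roughly doubles the phenotype-PGS information per family
relative to a parent-child trio design and, through the contrast of
monozygotic (MZ) and dizygotic (DZ) pairs, identifies the residual twin
covariance structure.

## The model

Each family contributes a six-variate observation
$(P_m, P_f, P_{t1}, P_{t2}, Y_1, Y_2)$: the PGS of mother, father and the
two twins, and the two twins' phenotype scores. The generative structure
is:

* Parental PGS are bivariate Gaussian with common variance $V_{PGS}$ and
  correlation $r_a$. The correlation absorbs both assortative mating and
  residual population stratification; it is what allows parent-child PGS
  correlations to exceed the Mendelian 0.5.
* Each twin's PGS is the mid-parent average plus a Mendelian segregation
  deviation: $P_{t} = 0.5\,P_m + 0.5\,P_f + s$. The 0.5 paths are fixed
  (each parent transmits exactly half their autosomes); the segregation
  variance is therefore not free but derived,
  $\mathrm{var}(s) = V_{PGS}(1-r_a)/2$, which keeps every family member's
  PGS variance equal to $V_{PGS}$. MZ co-twins share one deviation $s$
  (identical genomes); DZ co-twins draw independent deviations, giving the
  implied twin-PGS correlations 1 (MZ) and $0.5(1+r_a)$ (DZ).
* Each twin's phenotype is
  $Y_i = \mu + g_{tw} P_{t_i} + g_m P_m + g_f P_f + e_i$, with the
  residual pair $(e_1, e_2)$ bivariate Gaussian with variance $V_{ADHD}$
  and correlation $r_{MZ}$ or $r_{DZ}$ by zygosity. $g_{tw}$ is the direct
  transmission path; $g_m$ and $g_f$ are the nurture paths.

Ten parameters are estimated — $V_{PGS}$, $r_a$, $V_{ADHD}$, $r_{MZ}$,
$r_{DZ}$, $g_{tw}$, $g_m$, $g_f$ and the two means — with everything except
$r_{MZ}/r_{DZ}$ constrained equal across the MZ and DZ groups. The
model-implied moments are built two independent ways: by general
path-matrix (RAM) algebra in `implied_moments()` and from hard-coded
scalar formulas in `closed_form_moments()`; the test suite holds them to
within $10^{-10}$ of each other over random admissible parameters, so each
serves as the other's oracle. `describe_model()` prints the symbolic
covariance.

## Estimation: FIML over missingness patterns

Real family cohorts are incomplete — in the motivating study roughly a
quarter of all data points were missing, with many families missing one or
both parental genotypes. The likelihood is full-information maximum
likelihood: each family contributes the Gaussian log-density of whatever
subset of the six variables it was observed on, under the matching sub-mean
and sub-covariance of its zygosity group's implied moments. Nothing is
imputed. Families sharing a missingness pattern are grouped and evaluated
through pattern-level sufficient statistics (count, mean, scatter), which
makes one likelihood evaluation cost proportional to the number of
patterns rather than the number of families; the result is identical to
naive per-family evaluation, and the tests verify this against a dense
per-family oracle.

One numerical subtlety deserves its own paragraph. Because MZ co-twins
carry identical genomes, the implied MZ twin-PGS correlation is exactly 1
and the full six-variate MZ Gaussian is singular. When both MZ twin PGS
are observed and equal (which `propagate_mz_genotypes()` guarantees after
preprocessing), the duplicated entry carries no information and the
likelihood is evaluated on the reduced five-variate vector. The same
reduction is applied in the saturated and independence reference models,
so likelihood-ratio statistics and fit indices always compare models on
the same observation space; the saturated free-parameter count drops
accordingly (20 instead of 27 for a complete-data MZ group). Observed but
*unequal* MZ twin PGS are model-inconsistent and produce a flagged
`-Inf` likelihood rather than a silent fix.

Optimization runs on an unconstrained scale (log variances, atanh
correlations) with `nlminb`, analytic-free central-difference gradients
computed in compiled code, method-of-moments starting values from
pairwise-complete sample moments, and up to two jittered restarts on
non-convergence. Generous box bounds on the transformed scale keep
degenerate data (which can make the FIML likelihood unbounded, e.g. zero
within-pattern scatter) from running away; solutions at a bound are
flagged `boundary` and not reported as converged unless the gradient
criterion is also met.

Model adequacy is assessed the standard SEM way: a likelihood-ratio test
against the per-group saturated model (unstructured means and
covariances, themselves fitted by FIML so the comparison is valid under
missingness), plus CFI, TLI and RMSEA computed from the target, saturated
and independence-model log-likelihoods. The RMSEA sample size is the
number of families — the independent sampling units of the likelihood —
not the number of persons.

## Standardized effects and the variance decomposition

Raw paths depend on the scales of the PGS and the phenotype, so effects
are standardized with the *model-implied* variances:
$g' = g\sqrt{V_{PGS}/V_{phen}}$, where $V_{phen}$ is the implied phenotype
variance. The explained variance is split as:

* $R^2_{total} = (V_{phen} - V_{ADHD})/V_{phen}$ — everything the three
  PGS paths explain jointly;
* $R^2_{gt} = g_{tw}^2 V_{PGS} / V_{phen}$ — the share remaining after
  the *direct parental-path effects are removed* (the child path is kept,
  and the full-model $V_{phen}$ stays in the denominator);
* $R^2_{gn} = R^2_{total} - R^2_{gt}$ — everything that involves the
  parental paths, including the cross-covariance terms between the child
  and parental paths.

Those cross terms enter $R^2_{total}$ with the sign of
$g_{tw}(g_m + g_f)$. When the child and parental paths have opposite
signs — a negative passive gene-environment correlation — $R^2_{gn}$ is
negative and direct transmission *exceeds* the total explained variance.
This is not a pathology; it is a substantively meaningful signature, and
the decomposition is deliberately defined so it can surface. The identity
$R^2_{gn} = R^2_{total} - R^2_{gt}$ holds to machine precision by
construction, and $R^2_{total}$ is verified against the Monte-Carlo $R^2$
of the genetic composite under the generative model.

## Inference

Sampling uncertainty comes from a family-level nonparametric bootstrap:
families are resampled with replacement, stratified by zygosity so each
replicate keeps the original MZ and DZ counts, and the model is refitted
per replicate starting from the base-fit estimates (one jittered fallback
start). Intervals are percentile intervals — the minimal reading of a
bootstrap CI, isolated in `percentile_interval()` so the convention can be
swapped — with 10,000 replicates by default and levels 95% and 99.2%, the
latter being the Bonferroni level $1 - 0.05/6$ for three PGS effects
tested by two PGS (`multiplicity_level(0.05, 6)`). A quantity is flagged
significant when its interval excludes zero; non-converged replicates are
excluded and counted, and a result with more than 20% failures is flagged
unreliable. All resampling indices are pre-drawn from the seed, so results
are bit-for-bit reproducible and independent of the number of parallel
jobs. The presence of genetic nurture can alternatively be tested by the
2-df likelihood-ratio comparison of the full model against the
`fit_no_nurture()` model ($g_m = g_f = 0$); both routes are provided
because either may be wanted for a nurture claim.

## Preprocessing

Three small utilities reproduce the phenotype and PGS preparation stages.
`score_symptoms()` averages 0/1/2 symptom-item ratings within each
measurement occasion and then across occasions in a developmental period,
skipping unrated items and empty occasions, and returning `NA` (never
zero) when nothing was rated. `transform_adjust()` square-root transforms
the right-skewed period scores and removes mean sex differences by OLS
residualization, treating twins as separate observations; the ambiguity of
"transform within an adjusting linear model" is resolved as transform
first, then residualize, the simplest reading that yields one sex-adjusted
approximately Gaussian score per child. Whether to pool developmental
periods in one adjustment is left to the caller (run it per period or on
the pooled vector). `residualize_pgs()` regresses PGS on ancestry
covariates (typically 10 genetic principal components, supplied
precomputed), then re-standardizes over the pooled sample of parents and
twins — one scale for all family roles, consistent with the single
$V_{PGS}$ parameter. Preprocessing never imputes; missingness is the
likelihood's job. Point residuals are all the model needs, so the OLS
steps ignore the twin clustering deliberately.

## The simulator, and what passing tests do and do not show

`simulate_families()` draws complete data from exactly the generative
structure above; `inject_missingness()` blanks cells afterwards from an
independent seed, so toggling missingness never changes the underlying
complete data. Missingness is MCAR, either cell-wise at a global rate or
by fixed pattern counts of parental/twin genotype availability. The
defaults mirror the motivating cohort's design: 169 MZ + 246 DZ families;
`study_missingness()` gives the 159/67/189 both/one/no-parent and 378/37
twin-genotype pattern counts. The default parameters (`study_params()`) use
the study-scale magnitudes — child path 0.157, parental paths −0.089 and
−0.015 on the standardized scale, parental PGS correlation 0.07 — with
residual twin correlations 0.6 (MZ) and 0.3 (DZ), values typical of
childhood ADHD symptom ratings whose twin heritability is 50–70%, and
$V_{ADHD}$ set so the implied phenotype variance is exactly 1.

The simulator draws exactly the Gaussian, linear, MCAR world the model
assumes. Passing recovery and calibration tests therefore demonstrates
internal correctness — the estimator finds the truth of its own generative
model, test sizes are honest, intervals cover — but not robustness to what
real cohorts add: non-Gaussian symptom distributions, rater effects,
informative missingness, PGS measurement error, or dynastic effects across
generations. Those caveats transfer to any application.

## Validation choices and problem sizes

The test suite fixes its scales as follows: oracle equivalence of the two
moment constructions on 1,000 random parameter draws at $10^{-10}$; FIML
against a dense per-family Gaussian oracle on complete and 25%-missing
data; empirical moments of $10^5$ simulated DZ families against the
implied matrix within three standard errors per entry; parameter recovery
over 200 simulate-fit replicates of 2,000 families (all ten parameters
within three Monte-Carlo standard errors of truth) with the empirical SE
of $g'_{tw}$ halving, within 20%, from 1,000 to 4,000 families; the
decomposition identity at machine precision and its Monte-Carlo check at
$10^6$ draws; the 2-df nurture LRT holding its nominal 5% size within
[2.5%, 8%] over 500 null simulations; and 95% bootstrap coverage for
$g'_{tw}$ within [90%, 98%] over 200 simulations of 1,000 families with
500 replicates each. The pattern-sufficient-statistic likelihood in
compiled code is what makes the roughly 10^5 model fits behind these
checks routine.

## Known limitations

The model is univariate (one PGS, one phenotype at a time; multi-PGS or
multi-dimension runs are independent fits via `run_pipeline()`), assumes
equal residual phenotype variance across zygosity groups (only the
residual correlation differs), has no sex-limitation or longitudinal
structure, and offers no robust standard errors — the bootstrap is the
inferential tool. Percentile intervals can undercover for strongly skewed
statistics at small family counts. PGS measure genetic propensity with
error, so all paths are attenuated relative to true genetic effects, and
the $r_a$ parameter cannot distinguish assortative mating from residual
stratification.
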