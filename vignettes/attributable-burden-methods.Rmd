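---
title: "Methods: attributing disease burden to genetic exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing disease burden to genetic exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gendaly)
```

## The problem

A genetic exposure — a common risk allele, a rare loss-of-function burden,
or a polygenic score — typically raises the hazard of a handful of
diseases by a modest factor. How much population health does that cost?
`gendaly` answers in disability-adjusted life years (DALYs): the yearly
burden per 100,000 population attributable to the exposure, and the
expected lifetime healthy life years an exposed individual loses. The
pipeline is comparative risk assessment adapted to genetic exposures:
hazard ratios from survival models, a shrinkage step that decides which
exposure–disease effects are real, attributable fractions from a
counterfactual shift of exposure frequencies, and DALY rates taken from a
Global Burden of Disease (GBD) style table, which the analysis treats as
fixed and known.

All analyses here run on synthetic cohorts with known ground truth. The
generators emulate the statistical structure the estimators assume; what
they deliberately do not emulate is discussed at the end.

## Survival model

For each exposure $e$ and disease $d$ the association stage fits a Cox
proportional-hazards model with calendar age as the timescale, additive
in exposure level (allele count, carrier status, or a top-decile score
indicator), adjusted for sex and the cohort covariates, with Efron tie
handling. Individuals are censored at death or administrative end of
follow-up. The per-copy log hazard ratio $\hat\beta_{e,d}$ and its
standard error $\sigma_{e,d}$ feed everything downstream. Pairs with no
events, a monomorphic exposure, below a configurable case-count floor,
or a non-converged fit are flagged `non_estimable` and carried with a
status flag rather than silently dropped. When the same association is
estimated in several cohorts, estimates are combined by fixed-effects
inverse-variance weighting, $w_k = 1/\sigma_k^2$.

Two modelling simplifications mirror the estimator's own assumptions:
left truncation and relatedness are ignored, and a rare-exposure Firth
penalty is not implemented — the case-count floor stands in for it.
Convergence uses at most 100 Newton iterations at a relative tolerance
of $10^{-9}$ (the `survival::coxph` control we pass); failures are
flagged, not imputed.

## Spike-and-slab shrinkage

With 80 diseases per exposure, most fitted hazard ratios are sampling
noise. One exposure at a time, the prior on the true log HRs is

$$p_e \sim \mathrm{Beta}(\alpha=1,\ \beta=19), \qquad
  b_{e,d} \sim \mathrm{Bernoulli}(p_e)\,
  \tfrac12\!\left\{N(\mu, \sigma^2) + N(-\mu, \sigma^2)\right\},$$

with $\mu = 0.3$, $\sigma = 0.1$: a priori each exposure affects about
4 of 80 diseases (prior mean inclusion 0.05), with effects centred at
hazard ratios 1.35 (risk) or 0.74 (protective). The measurement model —
which the prior alone does not pin down — takes the usual normal
approximation to the Cox estimator,
$\hat\beta_{e,d} \sim N(b_{e,d}, \sigma_{e,d}^2)$. That choice makes the
slab integrable in closed form
($\hat\beta \sim N(\pm\mu, \sigma^2 + \sigma_{e,d}^2)$ given inclusion),
so the sampler can collapse the continuous effect out entirely.

`collapsed_gibbs()` alternates (i) a categorical draw of each disease's
label (null / slab$+$ / slab$-$) given $p_e$, labels being conditionally
independent given $p_e$, with (ii) a conjugate
$\mathrm{Beta}(\alpha + k,\ \beta + d - k)$ draw of $p_e$ given the
non-null count $k$. The default schedule keeps 10,000 draws after a
1,000-iteration burn-in; the posterior null probability is the kept-draw
frequency of the null label. One independent chain runs per exposure,
seeded `seed + exposure index`, with $p_e$ initialised at its prior mean
and labels at a prior draw. Pairs with posterior null probability
*strictly above* 10% are discarded; retained pairs carry their
**original, unshrunk** Cox estimates downstream — shrinkage here selects,
it does not shrink point estimates.

Because the collapsed state space is just $3^d$ labels,
`exact_posterior_null()` enumerates the posterior exactly for $d \le 12$.
It is the package's independent oracle: the test suite checks the Gibbs
sampler against it on random small problems, together with the
qualitative properties the model implies (monotonicity of the null
probability in $|\hat\beta|/\mathrm{se}$, sign-swap symmetry, and
borrowing of strength — a strong co-signal raises $p_e$ and thereby
lowers other diseases' null probabilities).

## From hazard ratios to DALYs

For exposure levels $i = 0, \dots, m$ with population frequencies $P_i$,
counterfactual frequencies $P'_i$ and per-level hazard ratios
$\mathrm{HR}_{d,i}$ (additive coding: $\mathrm{HR}_{d,i} = e^{i b_d}$),
the population-attributable fraction is the multilevel formula

$$\mathrm{AFp}_d =
  \frac{\sum_i P_i \mathrm{HR}_{d,i} - \sum_i P'_i \mathrm{HR}_{d,i}}
       {\sum_i P_i \mathrm{HR}_{d,i}},$$

interpreted as the fraction of cases (and, assuming equal DALYs per case
with and without the exposure, of DALYs) prevented were frequencies
shifted to $P'$. Worked numerically:

```{r}
lev <- exposure_levels(P = c(0.7, 0.2, 0.1), P_prime = c(0.9, 0, 0.1),
                       hr = c(1.00, 1.35, 1.82))
attributable_fraction(lev)
```

about 6.1% of cases prevented if all one-copy carriers had zero copies.
Then, per disease,

* population-attributable DALYs $= \mathrm{AFp}_d \times \mathrm{DALY}_d$
  (yearly, per 100,000), and
* individual-attributable DALYs $=$ population DALYs divided by the
  number of exposed per 100,000, times life expectancy at birth $L$ —
  the expected lifetime healthy life years an exposed individual loses.

Totals are sums across one exposure's retained diseases (discarded pairs
contribute exactly zero). Totals of *different* exposures must not be
added — joint counterfactuals are not additive — and the interface
never does so. A counterfactual can also be a reference population's
Hardy–Weinberg genotype frequencies
(`counterfactual_from_reference()`), which measures the burden due to an
allele's enrichment in the study population.

$L$ is a required input with no package default baked into results; the
synthetic analyses fix $L = 80$ years, a round value in the range of
high-income-country life expectancies. DALY rates enter per 100,000 per
year, as GBD publishes them.

## Uncertainty

Holding exposure frequencies and DALY rates fixed, single-disease
attributable DALYs are a smooth function of one log HR, so their CI
comes from the delta method with the analytic derivative of the
$b \mapsto \mathrm{AFp} \mapsto \mathrm{DALY}$ map (the tests check the
gradient against central finite differences at $10^{-6}$ relative
tolerance).

Totals need the joint distribution of the 80 log HRs, which are
correlated across comorbid diseases. The between-disease correlation
$\hat C_{ij}$ is the Pearson correlation of log HRs across exposures
classified **null for both diseases** — only then do the coefficients
reflect shared sampling variability rather than true effects. (The
source material describes this step ambiguously, as both "all the shrunk
log HRs" and "restricted to unshrunk variants"; the joint-null reading is
the only one consistent with its stated purpose, and is the one
implemented.) Entries with fewer than 10 contributing exposures — a
floor chosen to stabilise the estimate at synthetic scale — are set to
zero, and the matrix is repaired to positive semi-definiteness by
eigenvalue clipping before sampling, a no-op when already PSD.

`resample_total_dalys()` then draws
$b^* \sim N(\hat\beta_e,\ D_e \hat C D_e)$ ($D_e$ the diagonal SE
matrix) $B = 10{,}000$ times, recomputes the total through the full
attribution map per draw with the retained/discarded classification held
fixed, and reports the 2.5%/97.5% percentiles as the 95% CI with a
normal-approximation p-value $z = \mathrm{total}/\mathrm{sd(draws)}$. A
bootstrap over individuals is intentionally out of scope — the
resampling design replaces it. Sex differences in totals are tested by an
independent-strata z-test on the resampling SDs; overlap between strata
through shared model structure is ignored, a documented approximation.

## The synthetic world

`draw_true_effects()` samples ground-truth effect matrices from the same
spike-and-slab prior the shrinkage assumes. `generate_cohort()` draws
Hardy–Weinberg allele dosages, standard-normal scores and Bernoulli
burden carriers, then event ages from a constant (exponential)
per-disease baseline hazard multiplied by
$\exp(\sum_e b_{e,d} x_e + \gamma^\top z)$, with an independent
exponential death process and administrative censoring. Design choices,
each the simplest member of its family that satisfies proportional
hazards:

* **Exponential baselines**, because cumulative incidence then has the
  closed form $1 - e^{-\lambda t}$, so rates can be calibrated to target
  incidences (`hazard_for_incidence()`) and generator tests have exact
  oracles.
* **Entry at birth** by default (delayed entry available), so left
  truncation — which the estimator ignores anyway — never arises in the
  default tests.
* **Death as independent censoring**, not a competing cause-specific
  model.
* **Covariate effects $\gamma = 0$ by default**: confounding is not
  needed to test the pipeline arithmetic, and can be switched on.

`generate_summary_stats()` bypasses the survival stage with
$\hat\beta \sim N(b, \mathrm{se}^2)$ draws for fast shrinkage tests, and
`generate_daly_table()` fabricates a GBD-dialect rate table whose
"both" row is the equal-weight sex combination.

## The shrinkage-performance study

`run_shrinkage_evaluation()` measures how well the posterior null
probability separates truly null from truly causal variant–phenotype
pairs after a genome-wide significance screen, the situation the
shrinkage is actually used in. One panel of independent Hardy–Weinberg
genotypes (50,000 individuals × 5,000 SNPs, MAF uniform on 0.01–0.5) is
shared across four causal-proportion scenarios
$\pi \in \{0.001, 0.002, 0.005, 0.01\}$ — mirroring how a fixed genotype
resource would be reused. Per scenario: spike-and-slab liability effects,
per-phenotype heritability uniform on 0.10–0.60, 80 binary phenotypes cut
from liability at prevalences uniform on 0.05–0.30 (a plausible range for
registry diseases), a vectorised per-variant linear association scan
(with unstructured, unrelated individuals this is asymptotically
equivalent to the logistic or mixed-model scan it stands in for),
selection at $P < 5 \times 10^{-8}$, then the collapsed Gibbs under the
default prior. The AUC of $1 - $ null probability against the true
causal mask, across all selected variant–phenotype pairs, summarises
discrimination; the acceptance analysis reports the minimum across the
four $\pi$ values. With independent genotypes there is no LD leakage
between variants, so AUCs here run higher than they would on real,
LD-structured panels; the study is a scaled analog, not a replication.

The dimensions (50,000 × 5,000 × 80) were chosen so the whole study runs
in minutes on one core; the config scales up.

## What passing tests do and do not show

The generators produce exactly the world the estimators assume:
proportional hazards, independent loci, correct measurement model, DALY
rates without error. Passing tests therefore demonstrate that the
implementation computes its estimands correctly and that the uncertainty
machinery is calibrated under the model — not that the model is right
for any real cohort. Real data add LD between variants, registry coding
error, under-ascertainment, age-varying hazard ratios, relatedness and
population structure; none of these are simulated, and the pipeline's
robustness to them is out of scope here.

## Degenerate inputs and numerical conventions

* Frequency vectors must sum to 1 within $10^{-10}$; hazard ratios must
  be positive.
* All component likelihoods in the sampler are computed in log space and
  normalised by their maximum, so extreme $z$-scores cannot underflow
  all three labels simultaneously.
* A posterior null probability of exactly 0.10 is retained ("over 10%"
  is strict).
* Top-quantile encoding selects exactly $\lfloor qn \rfloor$
  individuals, breaking ties by stable original order.
* Enumeration beyond $d = 12$ (over half a million configurations) is
  refused with a pointer to the MCMC path; the sampler refuses
  non-positive SEs and schedules with no kept draws.
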