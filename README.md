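# gendaly

Attributable disease burden of genetic exposures, in disability-adjusted
life years (DALYs).

A genetic exposure — a common risk allele, a rare loss-of-function
burden, a polygenic score — raises the hazard of some diseases by a
modest factor. This package quantifies what that costs: the yearly DALYs
per 100,000 population attributable to the exposure, and the expected
lifetime healthy life years lost per exposed individual. It is written
for statistical geneticists and epidemiologists who want a tested,
synthetic-data-backed implementation of the comparative-risk-assessment
chain for genetic exposures.

## The method

For each exposure *e* and disease *d*:

1. **Association.** Cox proportional hazards on the age timescale,
   additive in exposure level, adjusted for sex and covariates, Efron
   ties; censoring at death or end of follow-up. Multiple cohorts are
   combined by fixed-effects inverse-variance meta-analysis
   (w<sub>k</sub> = 1/se<sub>k</sub>²).
2. **Shrinkage.** Per exposure, the true log HRs b<sub>e,d</sub> get a
   spike-and-slab prior: p<sub>e</sub> ~ Beta(1, 19);
   b<sub>e,d</sub> is 0 with probability 1 − p<sub>e</sub>, else drawn
   from ½N(0.3, 0.1²) + ½N(−0.3, 0.1²). A collapsed Gibbs sampler
   (10,000 kept draws; exact 3^d enumeration oracle for d ≤ 12) yields
   the posterior probability each pair is null; pairs over 10% are
   discarded, the rest keep their unshrunk Cox estimates.
3. **Attribution.** Multilevel population-attributable fraction

   AFp_d = (Σᵢ Pᵢ·HR_{d,i} − Σᵢ P′ᵢ·HR_{d,i}) / Σᵢ Pᵢ·HR_{d,i}

   over exposure levels i with population frequencies P and
   counterfactual frequencies P′ (e.g. all one-copy carriers to zero
   copies). Population DALYs = AFp_d × DALY_d (a GBD-style yearly rate
   per 100,000); individual DALYs divide by the exposed count per
   100,000 and multiply by life expectancy L.
4. **Uncertainty.** Delta method per disease; for totals, B = 10,000
   draws from N(β̂, D Ĉ D) where Ĉ is the between-disease correlation of
   log HRs across jointly-null exposures, with percentile CIs and
   normal-approximation p-values; independent-strata z-test for sex
   differences.

Every stage is exercised against synthetic cohorts with known ground
truth (Hardy–Weinberg genotypes, exponential proportional hazards,
liability-threshold binary phenotypes). See the methods vignette
(`vignettes/attributable-burden-methods.Rmd`) for assumptions, defaults
and limitations.

## Worked example

```r
library(gendaly)

# an allele with genotype frequencies 0.7/0.2/0.1 and per-copy HR 1.35;
# counterfactual: all one-copy carriers have zero copies instead
lev <- exposure_levels(P = c(0.7, 0.2, 0.1), P_prime = c(0.9, 0, 0.1),
                       hr = c(1.00, 1.35, 1.82))
attributable_fraction(lev)
#> [1] 0.06076389
```

6.1% of this disease's cases would be prevented under the
counterfactual. If the disease carries 1,000 yearly DALYs per 100,000
and life expectancy is 80 years:

```r
pop <- population_attributable_dalys(0.0608, "d1", data.frame(
  disease_id = "d1", sex = "both", dalys_per_100k = 1000))
pop
#> [1] 60.8
individual_attributable_dalys(pop, exposed_fraction = 0.2,
                              life_expectancy = 80)
#> [1] 0.2432
```

so carrying one copy costs an expected 0.24 healthy life years.

The `analysis/` scripts run the full chain on a simulated biobank
cohort (30,000 individuals, 6 exposures, 12 diseases):

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + DALY table + truth
Rscript analysis/02_fit_survival.R        # 72 Cox fits + IVW meta check
Rscript analysis/03_shrinkage.R           # null-probability filter
Rscript analysis/04_attribution_ci.R      # DALYs + resampling CIs
Rscript analysis/05_shrinkage_evaluation.R  # discrimination study
```

Stage 3 prints, for example:

```
Shrinkage funnel: 72 estimable -> 6 retained, 66 discarded
Truth agreement: 75% of true effects retained, 100% of nulls discarded
```

and stage 4 ranks exposures by total individual-attributable DALYs with
95% resampling CIs (negative totals are prevented burden from
protective effects).

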