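# Shared fixtures and independent oracles, all generated in code.

# Tiny survival dataset with distinct event times (no ties), used to check
# the Cox fit against a brute-force partial-likelihood maximiser.
tiny_survival_data <- function() {
  data.frame(
    entry  = rep(0, 6),
    stop   = c(2, 4, 5, 7, 8, 10),
    status = c(1, 1, 0, 1, 0, 1),
    x      = c(1, 0, 1, 1, 0, 0))
}

# Hand-written Cox partial log-likelihood (no ties, so Efron = Breslow =
# exact); independent of survival::coxph.
cox_partial_loglik <- function(beta, df) {
  ll <- 0
  for (i in which(df$status == 1)) {
    at_risk <- df$stop >= df$stop[i]
    ll <- ll + beta * df$x[i] - log(sum(exp(beta * df$x[at_risk])))
  }
  ll
}

# Closed-form probability that a disease event is observed under an
# exponential event hazard lam, independent exponential death hazard del,
# and administrative censoring at age T (entry at birth).
expected_observed_incidence <- function(lam, del, T) {
  lam / (lam + del) * (1 - exp(-(lam + del) * T))
}

# A small multi-exposure cohort reused by survival/pipeline tests.
make_toy_cohort <- function(n = 4000, seed = 101) {
  prior <- shrinkage_prior()
  eff <- draw_true_effects(3, 5, prior, seed = seed, p_e = 0)
  # one dominant true effect, one moderate, rest null
  eff$true_log_hr["exp1", "dis1"] <- 0.5
  eff$true_log_hr["exp2", "dis3"] <- 0.3
  eff$null_mask <- eff$true_log_hr == 0
  cfg <- cohort_config(
    n_individuals = n,
    exposures = list(list(id = "exp1", kind = "allele_dosage", maf = 0.3),
                     list(id = "exp2", kind = "allele_dosage", maf = 0.2),
                     list(id = "exp3", kind = "score")),
    n_diseases = 5,
    baseline_hazard = hazard_for_incidence(0.15, 70),
    end_of_followup = 70, death_hazard = 0.005)
  list(cohort = generate_cohort(cfg, eff, seed = seed + 1),
       effects = eff, config = cfg)
}

# Flat-likelihood prior: slab components numerically indistinguishable
# from the null component at beta_hat = 0, se = 1, so posteriors reduce
# to the prior.
flat_likelihood_prior <- function(alpha = 1, beta = 19) {
  shrinkage_prior(alpha = alpha, beta = beta, mu = 1e-9, sigma = 1e-6)
}
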