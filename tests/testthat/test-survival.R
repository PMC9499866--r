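test_that("exposure encodings match their definitions", {
  expect_equal(sum(encode_exposure(1:100, "top_quantile", q = 0.10)), 10)
  expect_equal(which(encode_exposure(1:100, "top_quantile", q = 0.10) == 1),
               91:100)
  d <- c(0, 1, 2, 1, 0)
  expect_identical(encode_exposure(d, "additive_dosage"), as.numeric(d))
  expect_identical(encode_exposure(c(0, 2, 0, 1), "carrier"), c(0, 1, 0, 1))
  expect_error(encode_exposure(numeric(0)), "empty")
  expect_error(encode_exposure(1:5, "top_quantile", q = 1), "q")

  # top-decile threshold of standard normals ~ the 0.9 normal quantile
  set.seed(14)
  x <- rnorm(1000)
  enc <- encode_exposure(x, "top_quantile", q = 0.10)
  expect_equal(sum(enc), 100)
  thr <- min(x[enc == 1])
  expect_lt(abs(thr - qnorm(0.9)), 0.15)

  # stable tie handling: exactly floor(q n) selected even with ties
  expect_equal(sum(encode_exposure(rep(1, 50), "top_quantile", q = 0.10)), 5)
})

test_that("Cox fit matches a brute-force partial-likelihood maximiser", {
  df <- tiny_survival_data()
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, 0, df = df)
  oracle_beta <- grid[which.max(ll)]

  coh <- structure(list(
    individuals = data.frame(id = 1:6, sex = rep(0:1, 3),
                             entry_age = df$entry, exit_age = df$stop,
                             death_age = NA_real_, x = df$x),
    event_age = matrix(ifelse(df$status == 1, df$stop, NA_real_),
                       ncol = 1, dimnames = list(NULL, "d1")),
    exposure_ids = "x", covariate_ids = character(0)), class = "cohort")
  est <- fit_cox(coh, "x", "d1", include_sex = FALSE)
  expect_equal(est$status, "ok")
  expect_equal(est$log_hr, oracle_beta, tolerance = 1e-3)
})

test_that("Cox fit recovers the generative log hazard ratio", {
  pr <- shrinkage_prior()
  eff <- draw_true_effects(1, 1, pr, seed = 2, p_e = 1)
  eff$true_log_hr[1, 1] <- 0.30
  cfg <- cohort_config(50000,
                       list(list(id = "e1", kind = "allele_dosage", maf = 0.3)),
                       n_diseases = 1,
                       baseline_hazard = hazard_for_incidence(0.10, 70))
  coh <- generate_cohort(cfg, eff, seed = 9)
  est <- fit_cox(coh, "e1", "dis1")
  expect_equal(est$status, "ok")
  expect_lt(abs(est$log_hr - 0.30), 3 * est$se)
})

test_that("permuted exposures give calibrated null z-scores", {
  fix <- make_toy_cohort(n = 2000, seed = 55)
  z <- numeric(20)
  for (s in 1:20) {
    coh <- fix$cohort
    set.seed(s)
    coh$individuals$exp3 <- sample(coh$individuals$exp3)
    est <- fit_cox(coh, "exp3", "dis2")
    z[s] <- est$log_hr / est$se
  }
  expect_gte(mean(abs(z) < 4), 0.95)
})

test_that("non-estimable pairs are flagged, not dropped", {
  fix <- make_toy_cohort(n = 300, seed = 66)
  coh <- fix$cohort
  coh$individuals$exp1 <- 1           # monomorphic exposure
  est <- fit_cox(coh, "exp1", "dis1")
  expect_equal(est$status, "non_estimable")
  expect_true(is.na(est$log_hr))
  # case-count filter
  est2 <- fit_cox(coh, "exp2", "dis1", min_events = 1e6)
  expect_equal(est2$status, "non_estimable")
})

test_that("Cox fit is invariant to id relabeling and timescale shift", {
  fix <- make_toy_cohort(n = 1500, seed = 77)
  coh <- fix$cohort
  base <- fit_cox(coh, "exp1", "dis1")

  perm <- sample(nrow(coh$individuals))
  coh2 <- coh
  coh2$individuals <- coh$individuals[perm, ]
  coh2$event_age <- coh$event_age[perm, , drop = FALSE]
  expect_equal(fit_cox(coh2, "exp1", "dis1")$log_hr, base$log_hr,
               tolerance = 1e-8)

  coh3 <- coh
  coh3$individuals$entry_age <- coh$individuals$entry_age + 10
  coh3$individuals$exit_age <- coh$individuals$exit_age + 10
  coh3$event_age <- coh$event_age + 10
  expect_equal(fit_cox(coh3, "exp1", "dis1")$log_hr, base$log_hr,
               tolerance = 1e-8)
})

test_that("binary exposure HR approximates the risk ratio for rare outcomes", {
  pr <- shrinkage_prior()
  eff <- draw_true_effects(1, 1, pr, seed = 4, p_e = 1)
  eff$true_log_hr[1, 1] <- 0.5
  cfg <- cohort_config(150000,
                       list(list(id = "b1", kind = "burden",
                                 carrier_freq = 0.3)),
                       n_diseases = 1,
                       baseline_hazard = hazard_for_incidence(0.015, 70),
                       death_hazard = 1e-6)
  coh <- generate_cohort(cfg, eff, seed = 10)
  est <- fit_cox(coh, "b1", "dis1")
  x <- coh$individuals$b1
  ev <- !is.na(coh$event_age[, 1])
  rr <- mean(ev[x == 1]) / mean(ev[x == 0])
  expect_lt(abs(exp(est$log_hr) / rr - 1), 0.1)
})

test_that("fixed-effects IVW meta-analysis matches closed forms", {
  # identical inputs: same point estimate, se shrinks by sqrt(2)
  two <- data.frame(log_hr = c(0.2, 0.2), se = c(0.1, 0.1))
  m <- meta_fixed_effects(two)
  expect_equal(m$log_hr, 0.2)
  expect_equal(m$se, 0.1 / sqrt(2))

  # hand-computed weights (100, 25)
  m2 <- meta_fixed_effects(data.frame(log_hr = c(0.1, 0.3), se = c(0.1, 0.2)))
  expect_equal(m2$log_hr, 0.14)
  expect_equal(m2$se, 1 / sqrt(125))

  # single estimate passes through
  one <- data.frame(exposure_id = "e", disease_id = "d",
                    log_hr = 0.42, se = 0.07)
  m3 <- meta_fixed_effects(one)
  expect_equal(m3$log_hr, 0.42)
  expect_equal(m3$se, 0.07)

  # mixed keys rejected
  expect_error(meta_fixed_effects(
    data.frame(exposure_id = c("a", "b"), log_hr = 0:1, se = c(1, 1))),
    "mix")

  # combined SE never exceeds the smallest input SE
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    est <- data.frame(log_hr = rnorm(k), se = runif(k, 0.01, 0.5))
    expect_lte(meta_fixed_effects(est)$se, min(est$se))
  }
})

test_that("IVW meta-analysis agrees with an independent implementation", {
  skip_if_not_installed("metafor")
  set.seed(8)
  est <- data.frame(log_hr = rnorm(5, 0.2, 0.1), se = runif(5, 0.05, 0.3))
  m <- meta_fixed_effects(est)
  rma <- metafor::rma(yi = est$log_hr, sei = est$se, method = "FE")
  expect_equal(m$log_hr, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
})

test_that("composite mortality score behaves like a linear predictor", {
  pr <- shrinkage_prior()
  eff <- draw_true_effects(2, 1, pr, seed = 6, p_e = 0)
  cfg <- cohort_config(20000,
                       list(list(id = "s1", kind = "score"),
                            list(id = "s2", kind = "score")),
                       n_diseases = 1,
                       baseline_hazard = hazard_for_incidence(0.05, 70),
                       end_of_followup = 70, death_hazard = 0.004)
  coh <- generate_cohort(cfg, eff, seed = 12)
  # impose a death effect of s1 (log HR 0.3) by regenerating death ages
  set.seed(13)
  rate <- 0.004 * exp(0.3 * coh$individuals$s1)
  death <- rexp(20000, rate)
  coh$individuals$death_age <- ifelse(death <= 70, death, NA_real_)
  coh$individuals$exit_age <- pmin(ifelse(is.na(death), 70, death), 70)

  lp <- composite_linear_predictor(coh, c("s1", "s2"))
  # s2 has no death effect: its coefficient contribution is ~0, so the
  # predictor is rank-dominated by s1
  expect_gt(cor(lp, coh$individuals$s1, method = "spearman"), 0.9)

  # single-score composite is a monotone transform of that score
  lp1 <- composite_linear_predictor(coh, "s1")
  expect_equal(cor(lp1, coh$individuals$s1, method = "spearman"), 1)

  # top-10% of the composite carries excess mortality
  top <- encode_exposure(lp, "top_quantile", q = 0.10)
  ind <- coh$individuals
  dfit <- survival::coxph(
    survival::Surv(entry_age, exit_age,
                   as.integer(!is.na(death_age) & death_age <= exit_age)) ~ top,
    data = cbind(ind, top = top))
  expect_gt(unname(coef(dfit)), 0)
})

test_that("pair enumeration reproduces the analysis bookkeeping", {
  manifest <- data.frame(
    exposure_id = c(paste0("cv", 1:25), paste0("pgs", 1:5)),
    class = rep(c("common_variant", "pgs"), c(25, 5)))
  pairs <- enumerate_pairs(manifest, paste0("dis", 1:12))
  expect_equal(nrow(pairs), 30 * 12)
  expect_equal(length(unique(pairs$exposure_id)), 30)
  expect_error(enumerate_pairs(data.frame(exposure_id = c("a", "a")), "d"),
               "duplicate")
})
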