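# build a shrinkage-style table from a matrix of log HRs (exposures x
# diseases), all classified null unless stated
as_shrunk <- function(B, retained = NULL) {
  if (is.null(retained)) retained <- matrix(FALSE, nrow(B), ncol(B))
  data.frame(exposure_id = rep(rownames(B), times = ncol(B)),
             disease_id = rep(colnames(B), each = nrow(B)),
             log_hr = as.numeric(B), se = 0.05,
             retained = as.logical(retained), stringsAsFactors = FALSE)
}

test_that("null-pair correlations reflect the noise structure", {
  set.seed(200)
  n_e <- 400
  # independent noise: off-diagonals near zero
  B <- matrix(rnorm(n_e * 4, 0, 0.05), n_e, 4,
              dimnames = list(paste0("e", 1:n_e), paste0("d", 1:4)))
  C <- estimate_loghr_correlation(as_shrunk(B))
  off <- C$C[upper.tri(C$C)]
  expect_true(mean(abs(off) < 3 / sqrt(n_e)) >= 0.95)
  expect_equal(diag(C$C), setNames(rep(1, 4), paste0("d", 1:4)))

  # correlated noise at rho = 0.5 between two diseases is recovered
  z <- rnorm(n_e)
  B2 <- cbind(d1 = 0.05 * (sqrt(0.5) * z + sqrt(0.5) * rnorm(n_e)),
              d2 = 0.05 * (sqrt(0.5) * z + sqrt(0.5) * rnorm(n_e)),
              d3 = rnorm(n_e, 0, 0.05))
  rownames(B2) <- paste0("e", 1:n_e)
  C2 <- estimate_loghr_correlation(as_shrunk(B2))
  expect_lt(abs(C2$C["d1", "d2"] - 0.5), 3 / sqrt(n_e) + 0.05)

  # duplicated disease column: perfect correlation
  B3 <- cbind(d1 = B2[, 1], d2 = B2[, 1])
  rownames(B3) <- paste0("e", 1:n_e)
  C3 <- estimate_loghr_correlation(as_shrunk(B3))
  expect_equal(C3$C["d1", "d2"], 1)
})

test_that("retained pairs and sparse pairs are excluded from correlations", {
  set.seed(201)
  B <- matrix(rnorm(40, 0, 0.05), 20, 2,
              dimnames = list(paste0("e", 1:20), c("d1", "d2")))
  ret <- matrix(FALSE, 20, 2); ret[1:15, 1] <- TRUE  # only 5 joint nulls
  C <- estimate_loghr_correlation(as_shrunk(B, ret), min_pairs = 10)
  expect_equal(C$C["d1", "d2"], 0)       # floored to zero
  expect_equal(C$n_pairs["d1", "d2"], 5L)
  expect_error(estimate_loghr_correlation(as_shrunk(B[, 1, drop = FALSE])),
               "2 diseases")
})

test_that("PSD repair clips eigenvalues and restores the unit diagonal", {
  expect_equal(nearest_psd_repair(diag(3)), diag(3))
  # an already-PSD matrix passes through unchanged
  P <- matrix(c(1, 0.4, 0.2, 0.4, 1, 0.3, 0.2, 0.3, 1), 3, 3)
  expect_equal(nearest_psd_repair(P), P, tolerance = 1e-12)
  # indefinite 3x3 (eigenvalue -0.2) gets repaired
  M <- matrix(c(1, 0.9, -0.6, 0.9, 1, 0.5, -0.6, 0.5, 1), 3, 3)
  ev_in <- eigen(M, symmetric = TRUE)$values
  expect_lt(min(ev_in), 0)
  R <- nearest_psd_repair(M)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-12)
  expect_equal(diag(R), rep(1, 3))
  expect_lte(max(abs(R - M)), abs(min(ev_in)) + 1e-8)
  expect_error(nearest_psd_repair(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("resampled totals collapse to the point estimate as SEs vanish", {
  tab <- data.frame(disease_id = c("d1", "d2"), sex = "both",
                    dalys_per_100k = c(1000, 500))
  est <- data.frame(disease_id = c("d1", "d2"), log_hr = c(0.3, 0.1),
                    se = 1e-10, retained = TRUE)
  res <- resample_total_dalys(est, diag(2), P = c(0.7, 0.2, 0.1),
                              P_prime = c(0.9, 0, 0.1), daly_table = tab,
                              life_expectancy = 80, n_draws = 500, seed = 4)
  expect_lt(diff(res$ci_ind), 1e-6)
  expect_equal(mean(res$draws_ind), res$total_ind_dalys, tolerance = 1e-6)
  expect_error(resample_total_dalys(est, diag(2), c(0.7, 0.2, 0.1),
                                    c(0.9, 0, 0.1), tab, 80, n_draws = 50),
               "100")
})

test_that("single-disease percentile CI matches the closed-form transform", {
  tab <- data.frame(disease_id = "d1", sex = "both", dalys_per_100k = 1000)
  est <- data.frame(disease_id = "d1", log_hr = 0.3, se = 0.05,
                    retained = TRUE)
  P <- c(0.7, 0.2, 0.1); Pp <- c(0.9, 0, 0.1)
  res <- resample_total_dalys(est, diag(1), P, Pp, tab, 80,
                              n_draws = 20000, seed = 5)
  # the AFp -> DALY map is monotone in b, so CI endpoints are the map
  # applied to the normal quantiles of b
  map <- function(b) {
    lev <- exposure_levels(P, Pp, hr_levels_additive(b))
    individual_attributable_dalys(
      attributable_fraction(lev) * 1000, 0.2, 80)
  }
  lo <- map(0.3 - qnorm(0.975) * 0.05); hi <- map(0.3 + qnorm(0.975) * 0.05)
  expect_equal(res$ci_ind[1], lo, tolerance = 0.02)
  expect_equal(res$ci_ind[2], hi, tolerance = 0.02)
  expect_true(res$ci_ind[1] <= res$ci_ind[2])
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("identity-correlation resampling equals independent resampling", {
  tab <- data.frame(disease_id = c("d1", "d2", "d3"), sex = "both",
                    dalys_per_100k = c(800, 400, 1200))
  est <- data.frame(disease_id = c("d1", "d2", "d3"),
                    log_hr = c(0.2, 0.05, -0.1), se = c(0.04, 0.08, 0.05),
                    retained = TRUE)
  P <- c(0.6, 0.3, 0.1); Pp <- c(0.9, 0, 0.1)
  res <- resample_total_dalys(est, diag(3), P, Pp, tab, 80,
                              n_draws = 4000, seed = 6)
  # independent oracle: per-disease univariate normal draws through the
  # same attribution map
  set.seed(999)
  tot <- numeric(4000)
  for (j in 1:3) {
    b <- rnorm(4000, est$log_hr[j], est$se[j])
    Eb <- exp(outer(b, 0:2))
    s <- Eb %*% P; sp <- Eb %*% Pp
    tot <- tot + as.numeric((s - sp) / s) * tab$dalys_per_100k[j]
  }
  tot <- tot / (1e5 * 0.3) * 80
  ks <- suppressWarnings(ks.test(res$draws_ind, tot))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-PSD correlation inputs are rejected with guidance", {
  tab <- data.frame(disease_id = c("d1", "d2", "d3"), sex = "both",
                    dalys_per_100k = 100)
  est <- data.frame(disease_id = c("d1", "d2", "d3"), log_hr = 0.1,
                    se = 0.05, retained = TRUE)
  M <- matrix(c(1, 0.9, -0.6, 0.9, 1, 0.5, -0.6, 0.5, 1), 3, 3)
  expect_error(resample_total_dalys(est, M, c(0.7, 0.2, 0.1),
                                    c(0.9, 0, 0.1), tab, 80, n_draws = 200),
               "nearest_psd_repair")
})

test_that("delta-method gradient matches central finite differences", {
  P <- c(0.7, 0.2, 0.1); Pp <- c(0.9, 0, 0.1)
  set.seed(210)
  for (i in 1:20) {
    b <- rnorm(1, 0, 0.4); daly <- runif(1, 100, 2000)
    dm <- delta_method_disease_ci(b, 0.05, P, Pp, daly,
                                  life_expectancy = 80)
    h <- 1e-6
    f <- function(bb) delta_method_disease_ci(bb, 0.05, P, Pp, daly,
                                              life_expectancy = 80)$estimate
    fd <- (f(b + h) - f(b - h)) / (2 * h)
    expect_equal(dm$gradient, fd, tolerance = 1e-6)
  }
})

test_that("delta-method CI width is first-order in the standard error", {
  P <- c(0.7, 0.2, 0.1); Pp <- c(0.9, 0, 0.1)
  w <- function(se) {
    dm <- delta_method_disease_ci(0.3, se, P, Pp, 1000)
    dm$ci_high - dm$ci_low
  }
  expect_lt(w(1e-9), 1e-6)                      # zero-width limit
  expect_equal(w(0.002) / w(0.001), 2, tolerance = 1e-3)
  expect_error(delta_method_disease_ci(0.3, 0, P, Pp, 1000), "positive")
})

test_that("delta and resampling CIs agree for one disease at small SE", {
  tab <- data.frame(disease_id = "d1", sex = "both", dalys_per_100k = 1000)
  est <- data.frame(disease_id = "d1", log_hr = 0.3, se = 0.01,
                    retained = TRUE)
  P <- c(0.7, 0.2, 0.1); Pp <- c(0.9, 0, 0.1)
  res <- resample_total_dalys(est, diag(1), P, Pp, tab, 80,
                              n_draws = 20000, seed = 7)
  dm <- delta_method_disease_ci(0.3, 0.01, P, Pp, 1000,
                                life_expectancy = 80,
                                exposed_fraction = 0.2)
  expect_lt(abs(res$ci_ind[1] / dm$ci_low - 1), 0.05)
  expect_lt(abs(res$ci_ind[2] / dm$ci_high - 1), 0.05)
})

test_that("sex-difference z-test behaves symmetrically", {
  same <- sex_difference_test(0.2, 0.2, 0.01, 0.01)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)

  diff <- sex_difference_test(0.27, 0.05, 0.015, 0.01)
  expect_lt(diff$p_value, 0.05)
  expect_gt(diff$z, 0)

  flip <- sex_difference_test(0.05, 0.27, 0.01, 0.015)
  expect_equal(flip$z, -diff$z)
  expect_equal(flip$p_value, diff$p_value)
  expect_error(sex_difference_test(1, 1, NA, 0.1), "SD")
})
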