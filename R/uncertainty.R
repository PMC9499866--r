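#' Between-disease correlation of log hazard ratios under the null
#'
#' Estimates the disease-by-disease correlation matrix \eqn{\hat C} used
#' to resample correlated log HR vectors. For each disease pair the
#' Pearson correlation is computed across the exposures whose estimates
#' were classified null by shrinkage for *both* diseases, so the
#' coefficients reflect shared sampling variability rather than true
#' effects. Pairs with fewer contributing exposures than `min_pairs` are
#' set to zero.
#'
#' @param shrunk Output of [shrink_estimates()]: per-pair `exposure_id`,
#'   `disease_id`, `log_hr`, `retained`.
#' @param min_pairs Minimum number of contributing exposures per entry
#'   (default 10).
#' @return A list of class `"loghr_correlation"` with `C` (the d x d
#'   correlation matrix, unit diagonal) and `n_pairs` (contributing
#'   exposure counts).
#' @export
estimate_loghr_correlation <- function(shrunk, min_pairs = 10L) {
  need <- c("exposure_id", "disease_id", "log_hr", "retained")
  stopifnot(all(need %in% names(shrunk)))
  diseases <- unique(shrunk$disease_id)
  d <- length(diseases)
  if (d < 2L) stop("need at least 2 diseases", call. = FALSE)
  exposures <- unique(shrunk$exposure_id)
  B <- matrix(NA_real_, length(exposures), d,
              dimnames = list(exposures, diseases))
  idx <- cbind(match(shrunk$exposure_id, exposures),
               match(shrunk$disease_id, diseases))
  # only null-classified coefficients enter; retained pairs stay NA
  B[idx[!shrunk$retained, , drop = FALSE]] <-
    shrunk$log_hr[!shrunk$retained]
  C <- diag(1, d)
  n_pairs <- matrix(0L, d, d)
  dimnames(C) <- dimnames(n_pairs) <- list(diseases, diseases)
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    ok <- !is.na(B[, i]) & !is.na(B[, j])
    n_pairs[i, j] <- n_pairs[j, i] <- sum(ok)
    if (sum(ok) >= min_pairs) {
      r <- stats::cor(B[ok, i], B[ok, j])
      if (is.finite(r)) C[i, j] <- C[j, i] <- r
    }
  }
  diag(n_pairs) <- colSums(!is.na(B))
  structure(list(C = C, n_pairs = n_pairs), class = "loghr_correlation")
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalue clipping: negative eigenvalues are set to zero and the
#' result rescaled back to unit diagonal. A matrix that is already PSD is
#' returned unchanged (up to numerical tolerance).
#'
#' @param C Symmetric matrix with unit diagonal.
#' @return A PSD correlation matrix of the same dimension.
#' @export
nearest_psd_repair <- function(C) {
  if (!is.matrix(C) || !isSymmetric(unname(C), tol = 1e-8))
    stop("'C' must be a symmetric matrix", call. = FALSE)
  eig <- eigen(C, symmetric = TRUE)
  if (all(eig$values >= -1e-12)) return(C)
  v <- pmax(eig$values, 0)
  out <- eig$vectors %*% (v * t(eig$vectors))
  s <- sqrt(diag(out))
  out <- out / tcrossprod(s)
  diag(out) <- 1
  dimnames(out) <- dimnames(C)
  out
}

#' Total attributable DALYs with a correlated-resampling confidence interval
#'
#' Draws `n_draws` log-HR vectors for one exposure from
#' \eqn{N(\hat\beta_e, D_e \hat C D_e)} — \eqn{D_e} the diagonal matrix
#' of standard errors, \eqn{\hat C} the between-disease correlation — and
#' recomputes total population- and individual-attributable DALYs for
#' each draw, holding the exposure frequencies, the DALY rates and the
#' retained/discarded classification fixed. The 2.5% and 97.5% (for
#' `ci_level` 0.95) percentiles of the resampled totals give the CI; the
#' p-value comes from the normal approximation
#' \eqn{z = \mathrm{total} / \mathrm{sd}(\mathrm{draws})}.
#'
#' @param estimates Data frame for one exposure: `disease_id`, `log_hr`,
#'   `se`, `retained` (all diseases, retained or not).
#' @param C Correlation matrix over the same diseases (a matrix or a
#'   `"loghr_correlation"`), required PSD — see [nearest_psd_repair()].
#' @param P,P_prime Exposure level frequencies shared across diseases.
#' @param daly_table DALY rate table.
#' @param life_expectancy Life expectancy at birth, years.
#' @param n_draws Number of resamples B (default 10,000, minimum 100).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param sex,n_levels,exposed_fraction Passed to [attribute_exposure()].
#' @return A list with `total_pop_dalys`, `total_ind_dalys`, their
#'   percentile CIs (`ci_pop`, `ci_ind`), `sd_pop`, `sd_ind`, `p_value`
#'   (for the individual-scale total), and the resampled totals
#'   (`draws_pop`, `draws_ind`).
#' @export
resample_total_dalys <- function(estimates, C, P, P_prime, daly_table,
                                 life_expectancy, n_draws = 10000L,
                                 ci_level = 0.95, seed = 1L, sex = "both",
                                 n_levels = 3L, exposed_fraction = NULL) {
  if (inherits(C, "loghr_correlation")) C <- C$C
  if (n_draws < 100L) stop("'n_draws' must be at least 100", call. = FALSE)
  d <- nrow(estimates)
  if (!is.matrix(C) || nrow(C) != d)
    stop("correlation matrix dimension does not match disease count",
         call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite; ",
         "apply nearest_psd_repair()", call. = FALSE)
  stopifnot(all(c("disease_id", "log_hr", "se", "retained") %in%
                  names(estimates)))

  point <- attribute_exposure(
    stats::setNames(estimates$log_hr, estimates$disease_id),
    estimates$retained, P, P_prime, daly_table, life_expectancy,
    sex = sex, n_levels = n_levels, exposed_fraction = exposed_fraction)

  set.seed(seed)
  Sigma <- (estimates$se %o% estimates$se) * C
  draws <- MASS::mvrnorm(n_draws, mu = estimates$log_hr, Sigma = Sigma)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = d)

  lev0 <- exposure_levels(P, P_prime, rep(1, length(P)),
                          exposed_fraction = exposed_fraction)
  daly_d <- vapply(estimates$disease_id, function(id) {
    row <- daly_table$disease_id == id & daly_table$sex == sex
    if (!any(row)) stop(sprintf("no DALY row for disease '%s', stratum '%s'",
                                id, sex), call. = FALSE)
    daly_table$dalys_per_100k[row][1L]
  }, 0)

  # vectorised AFp over draws: S(b) = sum_i P_i e^{i b}, per disease column
  lvl <- seq_len(n_levels) - 1L
  ret <- which(estimates$retained)
  totals_pop <- numeric(n_draws)
  if (length(ret) > 0L) {
    for (j in ret) {
      Eb <- exp(outer(draws[, j], lvl))          # n_draws x levels
      s  <- as.numeric(Eb %*% lev0$P)
      sp <- as.numeric(Eb %*% lev0$P_prime)
      totals_pop <- totals_pop + (s - sp) / s * daly_d[j]
    }
  }
  totals_ind <- totals_pop / (1e5 * lev0$exposed_fraction) * life_expectancy

  a <- (1 - ci_level) / 2
  sd_pop <- stats::sd(totals_pop); sd_ind <- stats::sd(totals_ind)
  tot_ind <- attr(point, "total_ind_dalys")
  p_value <- if (sd_ind > 0)
    2 * stats::pnorm(-abs(tot_ind / sd_ind)) else as.numeric(tot_ind == 0)
  list(per_disease = point,
       total_pop_dalys = attr(point, "total_pop_dalys"),
       total_ind_dalys = tot_ind,
       ci_pop = unname(stats::quantile(totals_pop, c(a, 1 - a))),
       ci_ind = unname(stats::quantile(totals_ind, c(a, 1 - a))),
       sd_pop = sd_pop, sd_ind = sd_ind, p_value = p_value,
       draws_pop = totals_pop, draws_ind = totals_ind)
}

#' Delta-method confidence interval for one disease's attributable DALYs
#'
#' Propagates the sampling variance of a single log HR through the map
#' \eqn{b \mapsto AFp(e^{ib}) \mapsto} attributable DALYs using the
#' analytic derivative. With \eqn{S(b) = \sum_i P_i e^{ib}} and
#' \eqn{S'(b) = \sum_i P'_i e^{ib}},
#' \eqn{AFp = (S - S')/S} and
#' \eqn{dAFp/db = (\dot S - \dot S')/S - (S - S')\dot S/S^2} where dots
#' denote \eqn{\sum_i i P_i e^{ib}}. The CI is the symmetric normal
#' interval on the chosen DALY scale.
#'
#' @param log_hr,se Point estimate and standard error of the per-copy log
#'   HR.
#' @param P,P_prime Level frequencies.
#' @param daly_rate Yearly DALYs per 100,000 for the disease.
#' @param life_expectancy If supplied, the CI is on the
#'   individual-attributable (lifetime) scale; otherwise on the
#'   population scale.
#' @param exposed_fraction Exposed fraction for the individual scale.
#' @param n_levels Number of additive levels.
#' @param ci_level Confidence level.
#' @return List with `estimate`, `gradient` (d DALYs / d b), `ci_low`,
#'   `ci_high`.
#' @export
delta_method_disease_ci <- function(log_hr, se, P, P_prime, daly_rate,
                                    life_expectancy = NULL,
                                    exposed_fraction = NULL, n_levels = 3L,
                                    ci_level = 0.95) {
  if (!is.numeric(se) || se <= 0) stop("'se' must be positive", call. = FALSE)
  lev <- exposure_levels(P, P_prime, hr_levels_additive(log_hr, n_levels),
                         exposed_fraction = exposed_fraction)
  lvl <- seq_len(n_levels) - 1L
  eb <- exp(lvl * log_hr)
  s   <- sum(lev$P * eb);        sp   <- sum(lev$P_prime * eb)
  ds  <- sum(lvl * lev$P * eb);  dsp  <- sum(lvl * lev$P_prime * eb)
  afp <- (s - sp) / s
  dafp <- (ds - dsp) / s - (s - sp) * ds / s^2
  scale <- daly_rate
  if (!is.null(life_expectancy))
    scale <- scale / (1e5 * lev$exposed_fraction) * life_expectancy
  est <- afp * scale
  grad <- dafp * scale
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- z * abs(grad) * se
  list(estimate = est, gradient = grad,
       ci_low = est - half, ci_high = est + half)
}

#' Two-sample z-test for a sex difference in total attributable DALYs
#'
#' Compares male and female totals using the resampling standard
#' deviations, treating the strata as independent:
#' \eqn{z = (T_m - T_f) / \sqrt{sd_m^2 + sd_f^2}}, two-sided normal
#' p-value.
#'
#' @param total_m,total_f Stratum totals.
#' @param sd_m,sd_f Resampling standard deviations of the totals.
#' @return List with `z` and `p_value`.
#' @export
sex_difference_test <- function(total_m, total_f, sd_m, sd_f) {
  if (!is.numeric(sd_m) || !is.numeric(sd_f) || is.na(sd_m) || is.na(sd_f))
    stop("both strata must carry resampling SDs", call. = FALSE)
  denom <- sqrt(sd_m^2 + sd_f^2)
  z <- if (denom > 0) (total_m - total_f) / denom else 0
  list(z = z, p_value = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
}
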