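# Retention rule: discard only when the posterior null probability is
# strictly above the threshold, so a pair at exactly the cutoff is kept.
retain_call <- function(null_prob, prior) null_prob <= prior$null_threshold

#' Collapsed Gibbs classification of one exposure's log hazard ratios
#'
#' For a single genetic exposure with observed log HRs \eqn{\hat\beta_j}
#' and standard errors \eqn{se_j} across diseases \eqn{j = 1..d}, runs a
#' collapsed Gibbs sampler over the three-way component labels
#' (null / slab+ / slab-) of the spike-and-slab model. The continuous
#' effect is integrated out analytically: under the slab the observation
#' is marginally \eqn{N(\pm\mu, \sigma^2 + se_j^2)}. The sampler
#' alternates label draws with a conjugate Beta update of the inclusion
#' proportion \eqn{p_e} and summarises the posterior null probability per
#' disease as the post-burn-in label frequency.
#'
#' A pair is retained when its posterior null probability does not exceed
#' the threshold: strictly greater than `null_threshold` means discard.
#'
#' @param log_hr Numeric vector of observed log HRs for one exposure.
#' @param se Positive standard errors, same length.
#' @param prior A [shrinkage_prior()].
#' @param n_iter Total MCMC iterations (default 11,000).
#' @param burn_in Burn-in iterations discarded (default 1,000), so the
#'   default keeps 10,000 posterior draws.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   before sampling.
#' @return A data frame with one row per disease: `null_prob`,
#'   `slab_plus_prob`, `slab_minus_prob`, `retained`; attribute `p_mean`
#'   holds the posterior mean inclusion proportion.
#' @seealso [exact_posterior_null()] for the exact enumeration oracle at
#'   small dimension, [shrink_estimates()] for whole estimate sets.
#' @export
collapsed_gibbs <- function(log_hr, se, prior = shrinkage_prior(),
                            n_iter = 11000L, burn_in = 1000L, seed = NULL) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  log_hr <- as.numeric(log_hr); se <- as.numeric(se)
  if (length(log_hr) != length(se) || length(log_hr) == 0L)
    stop("'log_hr' and 'se' must be non-empty and equal length", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  if (n_iter <= burn_in || burn_in < 0)
    stop("need n_iter > burn_in >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- .gibbs_one_exposure(log_hr, se, prior$alpha, prior$beta,
                             prior$mu, prior$sigma,
                             as.integer(n_iter), as.integer(burn_in))
  out <- data.frame(null_prob = fit$null_prob,
                    slab_plus_prob = fit$slab_plus_prob,
                    slab_minus_prob = fit$slab_minus_prob,
                    retained = retain_call(fit$null_prob, prior))
  if (!is.null(names(log_hr))) rownames(out) <- names(log_hr)
  attr(out, "p_mean") <- fit$p_mean
  out
}

#' Exact posterior null probabilities by 3^d enumeration
#'
#' Marginalises the spike-and-slab posterior exactly by enumerating all
#' three-way label configurations across the \eqn{d} diseases of one
#' exposure. Configuration weights are
#' \deqn{\frac{B(\alpha + k, \beta + d - k)}{B(\alpha, \beta)}
#'       \left(\tfrac{1}{2}\right)^k \prod_j L_j(\mathrm{label}_j)}
#' with \eqn{k} the non-null count, \eqn{L_j(\mathrm{null}) =
#' \phi(\hat\beta_j; 0, se_j^2)} and \eqn{L_j(\mathrm{slab}\pm) =
#' \phi(\hat\beta_j; \pm\mu, \sigma^2 + se_j^2)}. Serves as the
#' independent oracle against which the Gibbs sampler is checked; only
#' feasible for \eqn{d \le 12}.
#'
#' @inheritParams collapsed_gibbs
#' @return A data frame with per-disease exact `null_prob`,
#'   `slab_plus_prob`, `slab_minus_prob`.
#' @export
exact_posterior_null <- function(log_hr, se, prior = shrinkage_prior()) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  log_hr <- as.numeric(log_hr); se <- as.numeric(se)
  d <- length(log_hr)
  if (d == 0L || length(se) != d)
    stop("'log_hr' and 'se' must be non-empty and equal length", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  if (d > 12L)
    stop("enumeration over 3^d configurations is infeasible for d > 12; ",
         "use collapsed_gibbs()", call. = FALSE)

  # per-disease log-likelihood of each label
  ll <- rbind(null  = stats::dnorm(log_hr, 0, se, log = TRUE),
              plus  = stats::dnorm(log_hr,  prior$mu,
                                   sqrt(prior$sigma^2 + se^2), log = TRUE),
              minus = stats::dnorm(log_hr, -prior$mu,
                                   sqrt(prior$sigma^2 + se^2), log = TRUE))

  labels <- as.matrix(expand.grid(rep(list(0:2), d)))  # 3^d x d
  k <- rowSums(labels != 0L)
  logw <- lbeta(prior$alpha + k, prior$beta + d - k) -
    lbeta(prior$alpha, prior$beta) + k * log(0.5)
  for (j in seq_len(d))
    logw <- logw + ll[labels[, j] + 1L, j]
  w <- exp(logw - max(logw))
  w <- w / sum(w)

  out <- data.frame(
    null_prob       = vapply(seq_len(d), function(j) sum(w[labels[, j] == 0L]), 0),
    slab_plus_prob  = vapply(seq_len(d), function(j) sum(w[labels[, j] == 1L]), 0),
    slab_minus_prob = vapply(seq_len(d), function(j) sum(w[labels[, j] == 2L]), 0))
  if (!is.null(names(log_hr))) rownames(out) <- names(log_hr)
  out
}

#' Shrinkage classification of a whole estimate set
#'
#' Runs [collapsed_gibbs()] independently for every exposure in an
#' estimate table (one chain per exposure, seeded `seed + exposure index`
#' for reproducibility) and returns the per-pair posterior null
#' probabilities and retention calls.
#'
#' @param estimates Data frame with columns `exposure_id`, `disease_id`,
#'   `log_hr`, `se` (one row per pair; see [fit_cox_pairs()] /
#'   [generate_summary_stats()]).
#' @param prior A [shrinkage_prior()].
#' @param n_iter,burn_in MCMC schedule per exposure.
#' @param seed Integer base seed.
#' @return `estimates` with columns `null_prob` and `retained` appended.
#' @export
shrink_estimates <- function(estimates, prior = shrinkage_prior(),
                             n_iter = 11000L, burn_in = 1000L, seed = 1L) {
  need <- c("exposure_id", "disease_id", "log_hr", "se")
  if (!all(need %in% names(estimates)))
    stop("estimates must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  estimates$null_prob <- NA_real_
  estimates$retained <- NA
  exposures <- unique(estimates$exposure_id)
  for (i in seq_along(exposures)) {
    idx <- which(estimates$exposure_id == exposures[i])
    res <- collapsed_gibbs(estimates$log_hr[idx], estimates$se[idx],
                           prior = prior, n_iter = n_iter,
                           burn_in = burn_in, seed = seed + i)
    estimates$null_prob[idx] <- res$null_prob
    estimates$retained[idx] <- res$retained
  }
  estimates
}

#' Split an estimate set by the posterior null-probability filter
#'
#' Partitions shrinkage-classified estimates into the retained set — which
#' carries the original, unshrunk Cox point estimates and standard errors
#' downstream — and the discarded set, kept for the correlation-matrix
#' stage of the uncertainty procedure.
#'
#' @param shrunk Output of [shrink_estimates()] (must carry `retained`).
#' @return A list with data frames `retained` and `discarded`.
#' @export
filter_by_null_probability <- function(shrunk) {
  if (!"retained" %in% names(shrunk))
    stop("input must carry a 'retained' column from shrink_estimates()",
         call. = FALSE)
  list(retained = shrunk[shrunk$retained, , drop = FALSE],
       discarded = shrunk[!shrunk$retained, , drop = FALSE])
}
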