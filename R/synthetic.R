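#' Draw a ground-truth effect matrix from the spike-and-slab prior
#'
#' Generates the true per-copy log hazard ratios \eqn{b_{e,d}} for every
#' exposure-disease pair by sampling the spike-and-slab model
#' generatively: each exposure's inclusion proportion \eqn{p_e} is drawn
#' from \eqn{Beta(\alpha, \beta)}; each \eqn{b_{e,d}} is exactly zero with
#' probability \eqn{1 - p_e} and otherwise drawn from the 50:50 mixture
#' \eqn{\tfrac{1}{2} N(\mu, \sigma^2) + \tfrac{1}{2} N(-\mu, \sigma^2)}.
#'
#' @param n_exposures,n_diseases Positive counts.
#' @param prior A [shrinkage_prior()].
#' @param seed Integer seed.
#' @param p_e Optional fixed inclusion proportion(s) overriding the Beta
#'   draw (recycled over exposures); `p_e = 0` gives an all-null matrix.
#' @return An object of class `"effect_matrix"`: list with `true_log_hr`
#'   (exposures x diseases), `null_mask` (`TRUE` where the effect is
#'   exactly zero) and `inclusion_proportion` (per exposure).
#' @export
draw_true_effects <- function(n_exposures, n_diseases,
                              prior = shrinkage_prior(), seed = 1L,
                              p_e = NULL) {
  stopifnot(inherits(prior, "shrinkage_prior"),
            n_exposures >= 1, n_diseases >= 1)
  set.seed(seed)
  if (is.null(p_e)) {
    p <- stats::rbeta(n_exposures, prior$alpha, prior$beta)
  } else {
    if (any(p_e < 0 | p_e > 1)) stop("'p_e' must lie in [0, 1]", call. = FALSE)
    p <- rep_len(p_e, n_exposures)
  }
  nonnull <- matrix(stats::runif(n_exposures * n_diseases) < p,
                    n_exposures, n_diseases)
  sign <- ifelse(stats::runif(n_exposures * n_diseases) < 0.5, 1, -1)
  b <- matrix(0, n_exposures, n_diseases)
  k <- sum(nonnull)
  if (k > 0)
    b[nonnull] <- sign[nonnull] * prior$mu +
      stats::rnorm(k, 0, prior$sigma)
  dimnames(b) <- list(paste0("exp", seq_len(n_exposures)),
                      paste0("dis", seq_len(n_diseases)))
  nonnull <- structure(nonnull, dimnames = dimnames(b))
  structure(list(true_log_hr = b, null_mask = !nonnull,
                 inclusion_proportion = p),
            class = "effect_matrix")
}

#' Cohort generator configuration
#'
#' Describes a synthetic biobank-style cohort: exposure specifications,
#' per-disease baseline hazards, censoring and mortality.
#'
#' @param n_individuals Cohort size.
#' @param exposures List of exposure specs, each a list with `id`, `kind`
#'   (`"allele_dosage"`, `"score"` or `"burden"`), and for allele
#'   exposures `maf` in (0, 0.5\], for burdens `carrier_freq`. Score
#'   exposures are standard normal per individual.
#' @param n_diseases Number of diseases.
#' @param baseline_hazard Per-disease event rate (events per person-year),
#'   recycled over diseases. See [hazard_for_incidence()] to calibrate a
#'   rate to a target cumulative incidence.
#' @param end_of_followup Administrative censoring age, years.
#' @param entry_age_range Uniform entry-age range; default `c(0, 0)`
#'   (entry at birth, no delayed entry).
#' @param death_hazard Rate of the independent exponential
#'   censoring-by-death process (per person-year).
#' @param n_covariates Number of standard-normal covariates (population
#'   structure stand-ins).
#' @param gamma Per-covariate log-hazard effects shared by all diseases
#'   (default 0: no confounding).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_individuals, exposures, n_diseases,
                          baseline_hazard, end_of_followup = 70,
                          entry_age_range = c(0, 0), death_hazard = 0.005,
                          n_covariates = 2L, gamma = 0) {
  stopifnot(n_individuals >= 1, n_diseases >= 1,
            end_of_followup > 0, death_hazard > 0)
  if (any(baseline_hazard <= 0)) stop("all rates must be positive", call. = FALSE)
  for (ex in exposures) {
    if (!ex$kind %in% c("allele_dosage", "score", "burden"))
      stop("unknown exposure kind: ", ex$kind, call. = FALSE)
    if (ex$kind == "allele_dosage" &&
        (is.null(ex$maf) || ex$maf <= 0 || ex$maf > 0.5))
      stop("allele exposure needs maf in (0, 0.5]", call. = FALSE)
    if (ex$kind == "burden" &&
        (is.null(ex$carrier_freq) || ex$carrier_freq <= 0 || ex$carrier_freq > 1))
      stop("burden exposure needs carrier_freq in (0, 1]", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 exposures = exposures, n_diseases = as.integer(n_diseases),
                 baseline_hazard = rep_len(baseline_hazard, n_diseases),
                 end_of_followup = end_of_followup,
                 entry_age_range = entry_age_range,
                 death_hazard = death_hazard,
                 n_covariates = as.integer(n_covariates),
                 gamma = rep_len(gamma, n_covariates)),
            class = "cohort_config")
}

#' Baseline hazard rate achieving a target cumulative incidence
#'
#' For a constant (exponential) hazard, cumulative incidence by time
#' \eqn{t} is \eqn{1 - e^{-\lambda t}}, so
#' \eqn{\lambda = -\log(1 - \mathrm{incidence}) / t}.
#'
#' @param incidence Target cumulative incidence in (0, 1).
#' @param years Follow-up length.
#' @return The per-person-year rate.
#' @export
hazard_for_incidence <- function(incidence, years) {
  stopifnot(incidence > 0, incidence < 1, years > 0)
  -log(1 - incidence) / years
}

#' Generate a synthetic cohort under a proportional-hazards model
#'
#' Simulates a biobank-style cohort: allele dosages under Hardy-Weinberg
#' proportions, standard-normal scores, Bernoulli burden carriers; per
#' disease, event ages drawn from an exponential hazard
#' \eqn{\lambda_d \exp(\sum_e b_{e,d} x_e + \gamma^T z)} (log-linear,
#' additive in allele count); an independent exponential death process and
#' administrative censoring at the end of follow-up; only the first event
#' per disease is kept, and only events inside the observed window
#' (entry, exit\].
#'
#' @param config A [cohort_config()].
#' @param effects An `"effect_matrix"` whose dimensions match the config's
#'   exposures and diseases.
#' @param seed Integer seed; the cohort is a pure function of
#'   `(config, effects, seed)`.
#' @return An object of class `"cohort"`: list with `individuals` (data
#'   frame: `id`, `sex`, `entry_age`, `exit_age`, `death_age`, covariate
#'   and dosage columns) and `event_age` (individuals x diseases matrix,
#'   `NA` where no event was observed).
#' @export
generate_cohort <- function(config, effects, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(effects, "effect_matrix"))
  b <- effects$true_log_hr
  if (nrow(b) != length(config$exposures) || ncol(b) != config$n_diseases)
    stop("effect matrix dimensions do not match config", call. = FALSE)
  set.seed(seed)
  n <- config$n_individuals
  sex <- stats::rbinom(n, 1L, 0.5)
  entry <- stats::runif(n, config$entry_age_range[1], config$entry_age_range[2])

  Z <- matrix(stats::rnorm(n * config$n_covariates), n, config$n_covariates)
  colnames(Z) <- paste0("cov", seq_len(config$n_covariates))

  X <- matrix(0, n, length(config$exposures))
  colnames(X) <- vapply(config$exposures, `[[`, "", "id")
  for (j in seq_along(config$exposures)) {
    ex <- config$exposures[[j]]
    X[, j] <- switch(ex$kind,
      allele_dosage = stats::rbinom(n, 2L, ex$maf),
      score         = stats::rnorm(n),
      burden        = stats::rbinom(n, 1L, ex$carrier_freq))
  }

  death_age <- stats::rexp(n, config$death_hazard)
  exit <- pmin(death_age, config$end_of_followup)
  # guard against pathological zero-length follow-up
  exit <- pmax(exit, entry + 1e-8)

  cov_lp <- as.numeric(Z %*% config$gamma)
  event_age <- matrix(NA_real_, n, config$n_diseases,
                      dimnames = list(NULL, colnames(b)))
  for (d in seq_len(config$n_diseases)) {
    rate <- config$baseline_hazard[d] * exp(as.numeric(X %*% b[, d]) + cov_lp)
    t_d <- stats::rexp(n, rate)
    obs <- t_d > entry & t_d <= exit
    event_age[obs, d] <- t_d[obs]
  }

  individuals <- data.frame(id = seq_len(n), sex = sex, entry_age = entry,
                            exit_age = exit,
                            death_age = ifelse(death_age <= config$end_of_followup,
                                               death_age, NA_real_),
                            Z, X, check.names = FALSE)
  structure(list(individuals = individuals, event_age = event_age,
                 exposure_ids = colnames(X),
                 covariate_ids = colnames(Z)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d exposures, %d diseases, %d deaths\n",
              nrow(x$individuals), length(x$exposure_ids),
              ncol(x$event_age), sum(!is.na(x$individuals$death_age))))
  invisible(x)
}

#' Generate summary statistics directly from true effects
#'
#' Fast path for testing the shrinkage and attribution stages without
#' survival fits: each pair's observed log HR is the true effect plus
#' normal noise at the prescribed standard error,
#' \eqn{\hat\beta_{e,d} \sim N(b_{e,d}, se^2)}.
#'
#' @param effects An `"effect_matrix"`.
#' @param se Standard error(s), strictly positive; scalar or a matrix
#'   matching `effects`.
#' @param seed Integer seed.
#' @return A data frame with columns `exposure_id`, `disease_id`,
#'   `log_hr`, `se`, `true_log_hr`.
#' @export
generate_summary_stats <- function(effects, se, seed = 1L) {
  stopifnot(inherits(effects, "effect_matrix"))
  b <- effects$true_log_hr
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  se_mat <- if (is.matrix(se)) se else matrix(se, nrow(b), ncol(b))
  set.seed(seed)
  obs <- b + stats::rnorm(length(b), 0, se_mat)
  data.frame(exposure_id = rep(rownames(b), times = ncol(b)),
             disease_id = rep(colnames(b), each = nrow(b)),
             log_hr = as.numeric(obs), se = as.numeric(se_mat),
             true_log_hr = as.numeric(b),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic disease-level DALY rate table
#'
#' Emulates a Global Burden of Disease style table of yearly DALYs per
#' 100,000 population by disease and sex. For each disease a total burden
#' is drawn uniformly from `magnitude_range` and split into male and
#' female rows at a male:female ratio drawn from `sex_ratio_range`; the
#' `"both"` row is the equal-weight population combination of the sexes.
#'
#' @param disease_ids Non-empty character vector.
#' @param magnitude_range Range (low, high) of the "both" DALY rate,
#'   per 100,000 per year.
#' @param sex_ratio_range Range of the male:female rate ratio.
#' @param seed Integer seed.
#' @return Data frame with columns `disease_id`, `sex` (male / female /
#'   both) and `dalys_per_100k`.
#' @export
generate_daly_table <- function(disease_ids, magnitude_range = c(50, 2000),
                                sex_ratio_range = c(0.5, 2), seed = 1L) {
  if (length(disease_ids) == 0L) stop("empty disease list", call. = FALSE)
  if (magnitude_range[1] <= 0 || magnitude_range[1] > magnitude_range[2])
    stop("need 0 < low <= high in 'magnitude_range'", call. = FALSE)
  set.seed(seed)
  k <- length(disease_ids)
  both <- stats::runif(k, magnitude_range[1], magnitude_range[2])
  ratio <- stats::runif(k, sex_ratio_range[1], sex_ratio_range[2])
  male <- both * 2 * ratio / (1 + ratio)
  female <- both * 2 / (1 + ratio)
  data.frame(disease_id = rep(disease_ids, each = 3L),
             sex = rep(c("male", "female", "both"), times = k),
             dalys_per_100k = as.numeric(rbind(male, female, both)),
             stringsAsFactors = FALSE)
}
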