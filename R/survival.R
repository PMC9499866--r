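#' Encode per-individual exposure values for survival analysis
#'
#' Three schemes cover the exposure classes used in the pipeline:
#' `additive_dosage` passes allele dosages through unchanged;
#' `top_quantile` dichotomises a continuous score at its upper tail (the
#' top-decile-versus-rest coding used for polygenic scores), with ties
#' broken by stable original ordering so exactly `floor(q * n)`
#' individuals are coded 1; `carrier` codes any positive value as 1.
#'
#' @param values Non-empty numeric vector.
#' @param scheme `"additive_dosage"`, `"top_quantile"` or `"carrier"`.
#' @param q Upper-tail fraction for `top_quantile`, in (0, 1); default 0.10.
#' @return Numeric vector of encoded exposure levels.
#' @export
encode_exposure <- function(values, scheme = c("additive_dosage",
                                               "top_quantile", "carrier"),
                            q = 0.10) {
  scheme <- match.arg(scheme)
  if (length(values) == 0L) stop("empty exposure vector", call. = FALSE)
  switch(scheme,
    additive_dosage = as.numeric(values),
    carrier = as.numeric(values > 0),
    top_quantile = {
      if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)", call. = FALSE)
      k <- floor(q * length(values))
      out <- numeric(length(values))
      if (k > 0) out[order(-values)[seq_len(k)]] <- 1  # stable tie-break
      out
    })
}

#' Cox proportional-hazards fit for one exposure-disease pair
#'
#' Fits `survival::coxph` with calendar age as the timescale (counting
#' process entry/exit), the exposure entered additively, sex and the
#' configured covariates adjusted for, Efron tie handling, and individuals
#' censored at death or end of follow-up. Pairs with no events, no
#' exposure variation among those at risk, or a non-converged fit are
#' flagged `non_estimable` rather than dropped, so downstream filters stay
#' explicit.
#'
#' @param cohort A `"cohort"` from [generate_cohort()].
#' @param exposure_id One of the cohort's exposure columns, or the name of
#'   a column supplied via `extra_exposure`.
#' @param disease_id One of the cohort's disease columns.
#' @param covariates Covariate columns to adjust for (default: all of the
#'   cohort's covariates).
#' @param include_sex Adjust for sex (default `TRUE`).
#' @param extra_exposure Optional per-individual numeric vector used as
#'   the exposure instead of a stored dosage column (e.g. an encoded
#'   composite score).
#' @param min_events Minimum number of events required for estimation
#'   (case-count power filter); below it the pair is flagged.
#' @param sex_stratum Fit on `"both"` sexes (default) or one stratum
#'   (`"male"` / `"female"`; sex is then dropped from the adjustment).
#' @return One-row data frame: `exposure_id`, `disease_id`, `log_hr`,
#'   `se`, `n_events`, `status` (`"ok"` or `"non_estimable"`),
#'   `sex_stratum`.
#' @export
fit_cox <- function(cohort, exposure_id, disease_id,
                    covariates = cohort$covariate_ids, include_sex = TRUE,
                    extra_exposure = NULL, min_events = 1L,
                    sex_stratum = c("both", "male", "female")) {
  stopifnot(inherits(cohort, "cohort"))
  sex_stratum <- match.arg(sex_stratum)
  if (sex_stratum != "both") include_sex <- FALSE  # constant within stratum
  ind <- cohort$individuals
  keep <- switch(sex_stratum, both = rep(TRUE, nrow(ind)),
                 male = ind$sex == 1L, female = ind$sex == 0L)
  ind <- ind[keep, , drop = FALSE]
  ev <- cohort$event_age[keep, disease_id]

  x <- if (is.null(extra_exposure)) ind[[exposure_id]] else extra_exposure[keep]
  status <- as.integer(!is.na(ev))
  stop_t <- ifelse(status == 1L, ev, ind$exit_age)
  n_events <- sum(status)

  fail <- function() data.frame(
    exposure_id = exposure_id, disease_id = disease_id,
    log_hr = NA_real_, se = NA_real_, n_events = n_events,
    status = "non_estimable", sex_stratum = sex_stratum,
    stringsAsFactors = FALSE)

  if (n_events < max(1L, min_events) || length(unique(x)) < 2L) return(fail())

  df <- data.frame(entry = ind$entry_age, stop = stop_t, status = status,
                   exposure = x)
  rhs <- "exposure"
  if (include_sex) { df$sex <- ind$sex; rhs <- c(rhs, "sex") }
  for (cv in covariates) { df[[cv]] <- ind[[cv]]; rhs <- c(rhs, cv) }
  form <- stats::as.formula(paste("survival::Surv(entry, stop, status) ~",
                                  paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients["exposure"])) return(fail())
  se <- sqrt(diag(fit$var))[which(names(fit$coefficients) == "exposure")]
  if (!is.finite(se) || se <= 0) return(fail())
  data.frame(exposure_id = exposure_id, disease_id = disease_id,
             log_hr = unname(fit$coefficients["exposure"]), se = unname(se),
             n_events = n_events, status = "ok", sex_stratum = sex_stratum,
             stringsAsFactors = FALSE)
}

#' Cox fits for all exposure-disease pairs of a cohort
#'
#' @inheritParams fit_cox
#' @param exposure_ids,disease_ids Subsets to fit (defaults: all).
#' @return Data frame of stacked [fit_cox()] rows.
#' @export
fit_cox_pairs <- function(cohort, exposure_ids = cohort$exposure_ids,
                          disease_ids = colnames(cohort$event_age),
                          covariates = cohort$covariate_ids,
                          include_sex = TRUE, min_events = 1L,
                          sex_stratum = "both") {
  res <- vector("list", length(exposure_ids) * length(disease_ids))
  k <- 0L
  for (e in exposure_ids) for (d in disease_ids) {
    k <- k + 1L
    res[[k]] <- fit_cox(cohort, e, d, covariates = covariates,
                        include_sex = include_sex, min_events = min_events,
                        sex_stratum = sex_stratum)
  }
  do.call(rbind, res)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort estimates of the same exposure-disease association
#' with weights \eqn{w_k = 1/se_k^2}: combined log HR
#' \eqn{\sum w_k \hat\beta_k / \sum w_k}, combined standard error
#' \eqn{(\sum w_k)^{-1/2}}.
#'
#' @param estimates Data frame with columns `log_hr` and `se` (one row per
#'   cohort) for a single (exposure, disease, stratum); identifier columns,
#'   when present, must be constant and are carried through.
#' @return A one-row data frame with the combined `log_hr`, `se` and the
#'   summed `n_events` when available.
#' @export
meta_fixed_effects <- function(estimates) {
  if (nrow(estimates) < 1L) stop("need at least one estimate", call. = FALSE)
  if (any(estimates$se <= 0)) stop("all standard errors must be positive",
                                   call. = FALSE)
  for (key in intersect(c("exposure_id", "disease_id", "sex_stratum"),
                        names(estimates)))
    if (length(unique(estimates[[key]])) > 1L)
      stop("estimates mix keys in column '", key, "'", call. = FALSE)
  w <- 1 / estimates$se^2
  out <- estimates[1L, , drop = FALSE]
  out$log_hr <- sum(w * estimates$log_hr) / sum(w)
  out$se <- 1 / sqrt(sum(w))
  if ("n_events" %in% names(estimates)) out$n_events <- sum(estimates$n_events)
  if ("cohort_id" %in% names(estimates)) out$cohort_id <- "meta"
  rownames(out) <- NULL
  out
}

#' Composite mortality score from multiple polygenic scores
#'
#' Fits a single Cox model of death on all listed score exposures plus sex
#' and the cohort covariates, then returns each individual's linear
#' predictor evaluated with sex fixed at 0.5 and covariates at 0 (their
#' mean), so the result depends on the scores only up to an additive
#' constant and can itself be used as a score-type exposure via
#' [encode_exposure()].
#'
#' @param cohort A `"cohort"` with observed deaths.
#' @param score_ids Exposure columns entering the mortality model.
#' @return Numeric vector, one linear-predictor value per individual.
#' @export
composite_linear_predictor <- function(cohort, score_ids) {
  stopifnot(inherits(cohort, "cohort"), length(score_ids) >= 1L)
  ind <- cohort$individuals
  death <- as.integer(!is.na(ind$death_age) & ind$death_age <= ind$exit_age)
  if (sum(death) == 0L) stop("no deaths observed in cohort", call. = FALSE)
  df <- data.frame(entry = ind$entry_age, stop = ind$exit_age,
                   status = death, sex = ind$sex)
  rhs <- c(score_ids, "sex", cohort$covariate_ids)
  for (v in c(score_ids, cohort$covariate_ids)) df[[v]] <- ind[[v]]
  form <- stats::as.formula(paste("survival::Surv(entry, stop, status) ~",
                                  paste(rhs, collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron")
  cf <- stats::coef(fit)
  lp <- as.numeric(as.matrix(ind[, score_ids, drop = FALSE]) %*%
                     cf[score_ids]) + 0.5 * cf["sex"]
  unname(lp)
}

#' Enumerate all exposure-disease analysis pairs from a manifest
#'
#' The pipeline's bookkeeping: every exposure in the manifest is paired
#' with every disease, reproducing the count of survival analyses the
#' association stage performs.
#'
#' @param manifest Data frame with a column `exposure_id` (one row per
#'   exposure; extra columns such as an exposure class are carried
#'   through).
#' @param disease_ids Character vector of disease identifiers.
#' @return Data frame of all (exposure, disease) pairs.
#' @export
enumerate_pairs <- function(manifest, disease_ids) {
  stopifnot("exposure_id" %in% names(manifest), length(disease_ids) >= 1L)
  if (anyDuplicated(manifest$exposure_id))
    stop("duplicate exposure ids in manifest", call. = FALSE)
  out <- merge(manifest, data.frame(disease_id = disease_ids), by = NULL)
  out[order(match(out$exposure_id, manifest$exposure_id)), , drop = FALSE]
}
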