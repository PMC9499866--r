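#' Exposure level set: frequencies, counterfactual frequencies and HRs
#'
#' Bundles the quantities entering the multilevel population-attributable
#' fraction: the ordered exposure levels (for an allele, copies 0/1/2), the
#' population frequencies `P` at each level, the counterfactual frequencies
#' `P_prime`, per-level hazard ratios (level 0 is the reference, HR = 1),
#' and the fraction of the population whose level differs between the two
#' frequency vectors (the denominator of individual-attributable DALYs).
#'
#' @param P Numeric vector of level frequencies, non-negative, summing to 1.
#' @param P_prime Counterfactual frequencies, same length, summing to 1.
#' @param hr Per-level hazard ratios for one disease (first element 1), or a
#'   matrix with one row per disease and one column per level. Use
#'   [hr_levels_additive()] to build per-level HRs from an additive
#'   per-copy log HR.
#' @param exposed_fraction Fraction of the population whose exposure level
#'   changes between `P` and `P_prime`. Defaults to the total frequency
#'   moved, \eqn{\sum_i \max(P_i - P'_i, 0)}.
#' @return An object of class `"exposure_levels"`.
#' @examples
#' # the one-vs-zero-copies counterfactual for an allele with genotype
#' # frequencies 0.7 / 0.2 / 0.1 and per-copy HR 1.35:
#' lev <- exposure_levels(P = c(0.7, 0.2, 0.1),
#'                        P_prime = c(0.9, 0, 0.1),
#'                        hr = c(1, 1.35, 1.82))
#' attributable_fraction(lev)   # ~0.061
#' @export
exposure_levels <- function(P, P_prime, hr, exposed_fraction = NULL) {
  P <- as.numeric(P); P_prime <- as.numeric(P_prime)
  if (length(P) != length(P_prime))
    stop("'P' and 'P_prime' must have the same length", call. = FALSE)
  if (any(P < 0) || any(P_prime < 0))
    stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-10)
    stop("'P' must sum to 1 (tolerance 1e-10)", call. = FALSE)
  if (abs(sum(P_prime) - 1) > 1e-10)
    stop("'P_prime' must sum to 1 (tolerance 1e-10)", call. = FALSE)
  if (is.matrix(hr)) {
    if (ncol(hr) != length(P))
      stop("'hr' must have one column per exposure level", call. = FALSE)
  } else {
    hr <- matrix(as.numeric(hr), nrow = 1L)
    if (ncol(hr) != length(P))
      stop("'hr' must have one value per exposure level", call. = FALSE)
  }
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("hazard ratios must be positive and finite", call. = FALSE)
  if (is.null(exposed_fraction))
    exposed_fraction <- sum(pmax(P - P_prime, 0))
  if (exposed_fraction <= 0 || exposed_fraction > 1)
    stop("'exposed_fraction' must be in (0, 1]", call. = FALSE)
  structure(list(P = P, P_prime = P_prime, hr = hr,
                 exposed_fraction = exposed_fraction),
            class = "exposure_levels")
}

#' Per-level hazard ratios from an additive per-copy log hazard ratio
#'
#' Under an additive allele-count model the HR at level \eqn{i} is
#' \eqn{e^{i b}} for per-copy log HR \eqn{b} (so two copies of a HR-1.35
#' allele carry HR \eqn{1.35^2 \approx 1.82}).
#'
#' @param log_hr Per-copy log hazard ratio (scalar or vector over diseases).
#' @param n_levels Number of exposure levels (default 3: 0/1/2 copies).
#' @return Matrix with one row per element of `log_hr`, columns
#'   \eqn{e^{0}, e^{b}, \ldots, e^{(m-1)b}}.
#' @export
hr_levels_additive <- function(log_hr, n_levels = 3L) {
  stopifnot(is.numeric(log_hr), n_levels >= 2L)
  exp(outer(as.numeric(log_hr), seq_len(n_levels) - 1L))
}

#' Multilevel population-attributable fraction
#'
#' The fraction of disease cases attributable to the population's exposure
#' level frequencies deviating from counterfactual frequencies:
#' \deqn{AFp_d = \frac{\sum_i P_i HR_{d,i} - \sum_i P'_i HR_{d,i}}
#'                    {\sum_i P_i HR_{d,i}}.}
#' Negative values indicate prevented burden (a protective shift).
#'
#' @param levels An [exposure_levels()] object.
#' @param disease Row index into the HR matrix (default 1).
#' @return The attributable fraction, a scalar \eqn{\le 1}.
#' @export
attributable_fraction <- function(levels, disease = 1L) {
  stopifnot(inherits(levels, "exposure_levels"))
  hr <- levels$hr[disease, ]
  s  <- sum(levels$P * hr)
  sp <- sum(levels$P_prime * hr)
  (s - sp) / s
}

#' Population-attributable DALYs for one disease
#'
#' Multiplies the attributable fraction by the disease's yearly DALYs per
#' 100,000 population. The attributable fraction of cases is interpreted as
#' the attributable fraction of DALYs, which assumes cases with and without
#' the exposure accrue the same DALYs per case.
#'
#' @param afp Attributable fraction from [attributable_fraction()].
#' @param disease_id Disease identifier present in `daly_table`.
#' @param daly_table A data frame from [generate_daly_table()] or
#'   [read_daly_table()] with columns `disease_id`, `sex`, `dalys_per_100k`.
#' @param sex Stratum: `"both"` (default), `"male"` or `"female"`.
#' @return Attributable DALYs per year per 100,000 (negative = prevented).
#' @export
population_attributable_dalys <- function(afp, disease_id, daly_table,
                                          sex = "both") {
  stopifnot(is.numeric(afp), length(afp) == 1L)
  row <- daly_table$disease_id == disease_id & daly_table$sex == sex
  if (sum(row) == 0L)
    stop(sprintf("no DALY row for disease '%s', stratum '%s'",
                 disease_id, sex), call. = FALSE)
  afp * daly_table$dalys_per_100k[row][1L]
}

#' Individual-attributable DALYs
#'
#' Converts yearly population-attributable DALYs per 100,000 into expected
#' lifetime healthy life years lost per exposed individual: divide by the
#' number of exposed individuals per 100,000 and multiply by life
#' expectancy at birth \eqn{L}.
#'
#' @param pop_dalys Population-attributable DALYs per year per 100,000.
#' @param exposed_fraction Fraction of the population with the exposure,
#'   in (0, 1].
#' @param life_expectancy Life expectancy at birth, years.
#' @return Lifetime attributable DALYs per exposed individual.
#' @export
individual_attributable_dalys <- function(pop_dalys, exposed_fraction,
                                          life_expectancy) {
  stopifnot(is.numeric(pop_dalys))
  if (!is.numeric(exposed_fraction) || exposed_fraction <= 0 ||
      exposed_fraction > 1)
    stop("'exposed_fraction' must be in (0, 1]", call. = FALSE)
  if (!is.numeric(life_expectancy) || life_expectancy <= 0)
    stop("'life_expectancy' must be positive", call. = FALSE)
  pop_dalys / (1e5 * exposed_fraction) * life_expectancy
}

#' Total attributable DALYs across diseases for one exposure
#'
#' Sums per-disease attributable DALYs (population or individual scale)
#' over the retained diseases of a single exposure; discarded pairs
#' contribute exactly zero. Totals for different exposures must never be
#' added together — joint counterfactuals are not additive — so this
#' function only accepts the per-disease vector of one exposure.
#'
#' @param per_disease Numeric vector of per-disease attributable DALYs.
#' @return Their sum (0 for an empty vector).
#' @export
total_attributable_dalys <- function(per_disease) {
  stopifnot(is.numeric(per_disease))
  if (length(per_disease) == 0L) return(0)
  sum(per_disease)
}

#' Counterfactual frequencies from a reference-population allele frequency
#'
#' Builds the counterfactual level frequencies as Hardy-Weinberg genotype
#' proportions at a reference allele frequency while keeping the study
#' population's observed frequencies, so that the attributable fraction
#' measures the burden due to the allele's enrichment in the study
#' population relative to the reference.
#'
#' @param levels An [exposure_levels()] with 3 allele-count levels.
#' @param reference_allele_freq Reference-population allele frequency in
#'   \[0, 0.5\].
#' @return A new [exposure_levels()] with `P_prime` replaced by the
#'   Hardy-Weinberg proportions at the reference frequency. The exposed
#'   fraction is the total frequency mass shifted.
#' @export
counterfactual_from_reference <- function(levels, reference_allele_freq) {
  stopifnot(inherits(levels, "exposure_levels"))
  q <- reference_allele_freq
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 0.5)
    stop("'reference_allele_freq' must be in [0, 0.5]", call. = FALSE)
  if (length(levels$P) != 3L)
    stop("reference counterfactual requires 3 allele-count levels", call. = FALSE)
  p_prime <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  ef <- sum(pmax(levels$P - p_prime, 0))
  if (ef == 0) ef <- 1  # P == P_prime: AFp is 0, denominator immaterial
  exposure_levels(P = levels$P, P_prime = p_prime, hr = levels$hr,
                  exposed_fraction = ef)
}

#' Per-disease and total attributable DALYs for one exposure
#'
#' Applies the attributable-fraction, population-DALY and individual-DALY
#' maps across all diseases retained after shrinkage for one exposure.
#' Discarded diseases appear with zero attributable DALYs.
#'
#' @param log_hr Named numeric vector of per-copy (or per-unit) log HRs,
#'   names are disease ids.
#' @param retained Logical vector parallel to `log_hr`; `FALSE` entries
#'   contribute zero.
#' @param P,P_prime Level frequencies shared across diseases.
#' @param daly_table DALY rate table (see
#'   [population_attributable_dalys()]).
#' @param life_expectancy Life expectancy at birth, years.
#' @param sex Stratum used for DALY look-up.
#' @param n_levels Number of additive exposure levels.
#' @param exposed_fraction Optional override for the exposed fraction.
#' @return A data frame with one row per disease (`disease_id`, `log_hr`,
#'   `retained`, `afp`, `pop_dalys`, `ind_dalys`) plus attributes
#'   `total_pop_dalys` and `total_ind_dalys`.
#' @export
attribute_exposure <- function(log_hr, retained, P, P_prime, daly_table,
                               life_expectancy, sex = "both", n_levels = 3L,
                               exposed_fraction = NULL) {
  stopifnot(length(log_hr) == length(retained), !is.null(names(log_hr)))
  lev0 <- exposure_levels(P, P_prime, hr = rep(1, length(P)),
                          exposed_fraction = exposed_fraction)
  out <- data.frame(disease_id = names(log_hr),
                    log_hr = as.numeric(log_hr),
                    retained = as.logical(retained),
                    afp = 0, pop_dalys = 0, ind_dalys = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    if (!out$retained[k]) next
    lev <- exposure_levels(P, P_prime,
                           hr = hr_levels_additive(out$log_hr[k], n_levels),
                           exposed_fraction = lev0$exposed_fraction)
    afp <- attributable_fraction(lev)
    pd  <- population_attributable_dalys(afp, out$disease_id[k], daly_table,
                                         sex = sex)
    out$afp[k]       <- afp
    out$pop_dalys[k] <- pd
    out$ind_dalys[k] <- individual_attributable_dalys(
      pd, lev$exposed_fraction, life_expectancy)
  }
  attr(out, "total_pop_dalys") <- total_attributable_dalys(out$pop_dalys)
  attr(out, "total_ind_dalys") <- total_attributable_dalys(out$ind_dalys)
  out
}
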