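#' Spike-and-slab prior for exposure-disease log hazard ratios
#'
#' Constructs the prior used to classify each exposure's per-disease log
#' hazard ratios as null or non-null. For one exposure, the model is
#' \deqn{p_e \sim Beta(\alpha, \beta), \quad
#'       b_{e,d} \sim Bernoulli(p_e) \cdot
#'       \tfrac{1}{2}\{N(\mu, \sigma^2) + N(-\mu, \sigma^2)\},}
#' i.e. each log HR is exactly zero with probability \eqn{1 - p_e} and
#' otherwise drawn from a 50:50 mixture of normals centred at \eqn{\pm\mu}.
#' The defaults put prior mean 0.05 on the inclusion proportion (so 4
#' expected non-null diseases out of 80) with slab centres at hazard ratios
#' \eqn{e^{0.3} \approx 1.35} (risk) and \eqn{e^{-0.3} \approx 0.74}
#' (protective).
#'
#' @param alpha,beta Positive shape parameters of the Beta prior on the
#'   per-exposure inclusion proportion \eqn{p_e}.
#' @param mu Positive slab centre on the log HR scale.
#' @param sigma Positive slab standard deviation.
#' @param null_threshold Posterior null-probability cutoff in (0, 1);
#'   pairs whose posterior null probability is strictly above it are
#'   discarded downstream.
#' @return An object of class `"shrinkage_prior"`: a list with elements
#'   `alpha`, `beta`, `mu`, `sigma`, `null_threshold`.
#' @seealso [collapsed_gibbs()], [exact_posterior_null()],
#'   [draw_true_effects()]
#' @examples
#' pr <- shrinkage_prior()
#' prior_mean_inclusion(pr)            # 0.05
#' expected_nonnull_count(pr, 80)      # 4
#' slab_hr_centers(pr)                 # c(1.3499, 0.7408)
#' @export
shrinkage_prior <- function(alpha = 1, beta = 19, mu = 0.3, sigma = 0.1,
                            null_threshold = 0.10) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!is.numeric(null_threshold) || length(null_threshold) != 1L ||
      null_threshold <= 0 || null_threshold >= 1)
    stop("'null_threshold' must be in (0, 1)", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, mu = mu, sigma = sigma,
         null_threshold = null_threshold),
    class = "shrinkage_prior"
  )
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf(
    "Spike-and-slab prior: Beta(%g, %g) on inclusion, slab N(+/-%g, %g^2), null cutoff %g\n",
    x$alpha, x$beta, x$mu, x$sigma, x$null_threshold))
  invisible(x)
}

#' Closed-form analytics of the spike-and-slab prior
#'
#' `prior_mean_inclusion()` returns the prior mean of the inclusion
#' proportion, \eqn{\alpha / (\alpha + \beta)}.
#' `expected_nonnull_count()` returns the expected number of non-null
#' diseases per exposure, \eqn{d \cdot \alpha / (\alpha + \beta)}.
#' `slab_hr_centers()` returns the two slab centres on the hazard-ratio
#' scale, \eqn{(e^{\mu}, e^{-\mu})}.
#'
#' @param prior A [shrinkage_prior()].
#' @param n_diseases Number of diseases considered per exposure.
#' @return A numeric scalar (or length-2 vector for `slab_hr_centers`).
#' @export
prior_mean_inclusion <- function(prior) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  prior$alpha / (prior$alpha + prior$beta)
}

#' @rdname prior_mean_inclusion
#' @export
expected_nonnull_count <- function(prior, n_diseases) {
  stopifnot(inherits(prior, "shrinkage_prior"),
            is.numeric(n_diseases), n_diseases >= 1)
  n_diseases * prior_mean_inclusion(prior)
}

#' @rdname prior_mean_inclusion
#' @export
slab_hr_centers <- function(prior) {
  stopifnot(inherits(prior, "shrinkage_prior"))
  c(risk = exp(prior$mu), protective = exp(-prior$mu))
}
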