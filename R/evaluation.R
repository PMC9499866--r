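#' Configuration for the shrinkage-performance simulation study
#'
#' Defines a fully synthetic genome-wide association study used to
#' measure how well the spike-and-slab shrinkage separates truly null
#' from truly non-null variant-phenotype effects: independent
#' Hardy-Weinberg genotypes, spike-and-slab liability effects at several
#' causal proportions, heritabilities drawn uniformly, binary phenotypes
#' from a liability threshold at per-phenotype prevalences, a per-variant
#' association scan, a genome-wide significance screen, and the shrinkage
#' classifier.
#'
#' @param n_individuals,n_snps Study dimensions.
#' @param causal_proportions Causal-proportion scenarios \eqn{\pi}.
#' @param heritability_range Uniform range for per-phenotype liability
#'   heritability.
#' @param prevalence_range Uniform range for per-phenotype prevalence.
#' @param n_phenotypes Number of binary phenotypes.
#' @param significance_threshold Genome-wide screen p-value.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param seed Integer seed.
#' @return A list of class `"eval_config"`.
#' @export
eval_config <- function(n_individuals = 50000L, n_snps = 5000L,
                        causal_proportions = c(0.001, 0.002, 0.005, 0.01),
                        heritability_range = c(0.10, 0.60),
                        prevalence_range = c(0.05, 0.30),
                        n_phenotypes = 80L,
                        significance_threshold = 5e-8,
                        maf_range = c(0.01, 0.5), seed = 1L) {
  stopifnot(n_individuals >= 10, n_snps >= 2, n_phenotypes >= 1,
            all(causal_proportions > 0 & causal_proportions < 1),
            all(heritability_range > 0 & heritability_range < 1),
            all(prevalence_range > 0 & prevalence_range < 1),
            significance_threshold > 0, significance_threshold < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 causal_proportions = causal_proportions,
                 heritability_range = heritability_range,
                 prevalence_range = prevalence_range,
                 n_phenotypes = as.integer(n_phenotypes),
                 significance_threshold = significance_threshold,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "eval_config")
}

#' Simulate genotypes and spike-and-slab binary phenotypes
#'
#' Draws independent Hardy-Weinberg genotype dosages at MAFs uniform on
#' the configured range, samples each phenotype's causal variants with
#' probability \eqn{\pi}, standard-normal causal effects, scales
#' environmental noise so the genetic share of liability variance matches
#' the target heritability, and binarises liability at the
#' \eqn{(1 - \mathrm{prevalence})} empirical quantile.
#'
#' @param config An [eval_config()].
#' @param causal_proportion A single \eqn{\pi} scenario.
#' @param genotypes Optional precomputed dosage matrix (individuals x
#'   snps) reused across scenarios.
#' @param seed Seed for this scenario (default the config seed).
#' @return List with `genotypes`, `phenotypes` (0/1 matrix, individuals x
#'   phenotypes), and `truth` (list: `causal_mask` snps x phenotypes,
#'   `true_effects`, `heritability`, `prevalence`).
#' @export
simulate_binary_gwas <- function(config, causal_proportion,
                                 genotypes = NULL, seed = config$seed) {
  stopifnot(inherits(config, "eval_config"),
            causal_proportion > 0, causal_proportion < 1)
  n <- config$n_individuals; m <- config$n_snps; P <- config$n_phenotypes
  if (causal_proportion * m < 1)
    warning("expected causal count below 1 per phenotype; proceeding")
  set.seed(seed)
  if (is.null(genotypes)) {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    genotypes <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    storage.mode(genotypes) <- "double"
  }
  h2 <- stats::runif(P, config$heritability_range[1],
                     config$heritability_range[2])
  prev <- stats::runif(P, config$prevalence_range[1],
                       config$prevalence_range[2])
  causal_mask <- matrix(stats::runif(m * P) < causal_proportion, m, P)
  true_effects <- matrix(0, m, P)
  true_effects[causal_mask] <- stats::rnorm(sum(causal_mask))

  phenotypes <- matrix(0L, n, P)
  for (p in seq_len(P)) {
    idx <- which(causal_mask[, p])
    g <- if (length(idx) > 0L)
      as.numeric(genotypes[, idx, drop = FALSE] %*% true_effects[idx, p])
    else numeric(n)
    vg <- stats::var(g)
    noise_sd <- if (vg > 0) sqrt(vg * (1 - h2[p]) / h2[p]) else 1
    liab <- g + stats::rnorm(n, 0, noise_sd)
    phenotypes[, p] <- as.integer(liab > stats::quantile(liab, 1 - prev[p]))
  }
  list(genotypes = genotypes, phenotypes = phenotypes,
       truth = list(causal_mask = causal_mask, true_effects = true_effects,
                    heritability = h2, prevalence = prev))
}

#' Per-variant association scan of binary phenotypes
#'
#' Marginal linear-model score/Wald test of each phenotype on each
#' variant's dosage, vectorised through cross-products. With unrelated,
#' unstructured synthetic individuals this agrees asymptotically with a
#' logistic or mixed-model scan and is the package's desk-scale stand-in
#' for one. Monomorphic variants are flagged and excluded (`NA`
#' effects).
#'
#' @param genotypes Dosage matrix (individuals x snps).
#' @param phenotypes 0/1 matrix (individuals x phenotypes).
#' @return List of snps x phenotypes matrices `beta`, `se`, `p`, plus
#'   logical vector `monomorphic`.
#' @export
association_scan <- function(genotypes, phenotypes) {
  n <- nrow(genotypes)
  if (nrow(phenotypes) != n) stop("dimension mismatch", call. = FALSE)
  gbar <- colMeans(genotypes)
  # chunked to avoid materialising a full squared copy of the dosage matrix
  m <- ncol(genotypes)
  sxx <- numeric(m)
  for (blk in split(seq_len(m), ceiling(seq_len(m) / 500))) {
    gb <- genotypes[, blk, drop = FALSE]
    sxx[blk] <- colSums(gb * gb)
  }
  sxx <- sxx - n * gbar^2
  mono <- sxx <= 0
  Yc <- sweep(phenotypes, 2L, colMeans(phenotypes))
  syy <- colSums(Yc^2)
  sxy <- crossprod(genotypes, Yc)          # = sum (g)(y - ybar) = Sxy
  beta <- sxy / sxx
  rss <- pmax(sweep(-sxy^2 / sxx, 2L, syy, `+`), 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  beta[mono, ] <- NA_real_; se[mono, ] <- NA_real_; p[mono, ] <- NA_real_
  list(beta = beta, se = se, p = p, monomorphic = mono)
}

#' Shrinkage discrimination AUC after a significance screen
#'
#' Restricts to variants with at least one association below the
#' genome-wide threshold, runs the collapsed Gibbs shrinkage per selected
#' variant across all phenotypes, and computes the area under the ROC
#' curve of \eqn{1 - } posterior null probability against the true causal
#' mask over all selected variant-phenotype pairs.
#'
#' @param scan Output of [association_scan()].
#' @param truth Truth list from [simulate_binary_gwas()].
#' @param prior A [shrinkage_prior()].
#' @param threshold Significance screen (default 5e-8).
#' @param n_iter,burn_in MCMC schedule per variant.
#' @param seed Base seed (chains seeded `seed + variant index`).
#' @return List with `auc`, `n_selected` (variants passing the screen),
#'   `n_pairs`, and the per-pair `score` / `is_causal` vectors.
#' @export
shrinkage_auc <- function(scan, truth, prior = shrinkage_prior(),
                          threshold = 5e-8, n_iter = 11000L,
                          burn_in = 1000L, seed = 1L) {
  pmin_snp <- suppressWarnings(apply(scan$p, 1L, min, na.rm = TRUE))
  selected <- which(is.finite(pmin_snp) & pmin_snp < threshold)
  if (length(selected) == 0L)
    stop("no variant passes the significance screen; ",
         "increase sample size or effect sizes", call. = FALSE)
  P <- ncol(scan$p)
  score <- matrix(NA_real_, length(selected), P)
  for (i in seq_along(selected)) {
    j <- selected[i]
    res <- collapsed_gibbs(scan$beta[j, ], scan$se[j, ], prior = prior,
                           n_iter = n_iter, burn_in = burn_in,
                           seed = seed + j)
    score[i, ] <- 1 - res$null_prob
  }
  is_causal <- truth$causal_mask[selected, , drop = FALSE]
  if (length(unique(as.vector(is_causal))) < 2L)
    stop("selected pairs contain a single truth class; AUC undefined",
         call. = FALSE)
  roc <- pROC::roc(response = as.integer(as.vector(is_causal)),
                   predictor = as.vector(score), levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)), n_selected = length(selected),
       n_pairs = length(is_causal), score = as.vector(score),
       is_causal = as.vector(is_causal))
}

#' Run the full shrinkage-performance study across causal proportions
#'
#' Generates one genotype panel (shared across scenarios, as a fixed
#' genotype resource would be), then for each causal proportion simulates
#' phenotypes, scans, screens and scores shrinkage discrimination.
#'
#' @param config An [eval_config()].
#' @param verbose Print per-scenario progress.
#' @return Data frame with one row per causal proportion: `pi`,
#'   `n_selected`, `n_pairs`, `auc`.
#' @export
run_shrinkage_evaluation <- function(config = eval_config(),
                                     verbose = FALSE) {
  stopifnot(inherits(config, "eval_config"))
  set.seed(config$seed)
  maf <- stats::runif(config$n_snps, config$maf_range[1],
                      config$maf_range[2])
  G <- matrix(stats::rbinom(config$n_individuals * config$n_snps, 2L,
                            rep(maf, each = config$n_individuals)),
              config$n_individuals, config$n_snps)
  storage.mode(G) <- "double"
  out <- vector("list", length(config$causal_proportions))
  for (k in seq_along(config$causal_proportions)) {
    pi_k <- config$causal_proportions[k]
    sim <- simulate_binary_gwas(config, pi_k, genotypes = G,
                                seed = config$seed + k)
    scan <- association_scan(sim$genotypes, sim$phenotypes)
    res <- shrinkage_auc(scan, sim$truth,
                         threshold = config$significance_threshold,
                         seed = config$seed + 1000L * k)
    out[[k]] <- data.frame(pi = pi_k, n_selected = res$n_selected,
                           n_pairs = res$n_pairs, auc = res$auc)
    if (verbose)
      message(sprintf("pi = %g: %d variants selected, AUC = %.3f",
                      pi_k, res$n_selected, res$auc))
  }
  do.call(rbind, out)
}
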