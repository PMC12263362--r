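# Synthetic admixed case-control cohorts.
#
# Every downstream stage of the pipeline (ancestry estimation, scoring,
# risk modelling, reclassification) is exercised on cohorts produced here:
# Dirichlet admixture proportions over the five 1000 Genomes
# superpopulations, Balding-Nichols ancestry-specific allele frequencies,
# binomial genotypes, and a logistic case-control outcome whose intercept is
# solved so the marginal case rate matches the configured case fraction.

#' Simulation configuration for synthetic admixed cohorts
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults describe an AMR-dominant admixed case-control study: 1,997 women,
#' 25.5% cases, a per-SD odds ratio of 1.56 for the standardized PRS, and
#' BI-RADS density / family-history covariates whose effect sizes are the
#' unadjusted log odds ratios implied by the control and case density
#' distributions of such a cohort.
#'
#' @param n_individuals number of individuals.
#' @param case_fraction target marginal case rate, strictly in (0, 1).
#' @param n_variants number of biallelic variants.
#' @param ancestry_labels superpopulation codes; at least two.
#' @param dirichlet_alpha positive Dirichlet concentration, one per ancestry.
#'   The default gives mean proportions of roughly 3/75/1/20/1 percent for
#'   AFR/AMR/EAS/EUR/SAS.
#' @param true_or_per_sd odds ratio per standard deviation of the
#'   standardized PRS in the generative logistic model.
#' @param covariate_effects named list of log-odds effects:
#'   `density` (named vector over levels A-D, log-odds versus level A) and
#'   `family_history` (scalar log-odds for a positive family history).
#' @param density_probs marginal distribution of BI-RADS density A-D in the
#'   underlying population (case-status independent; effects act only
#'   through the outcome model).
#' @param family_history_prob marginal probability of a positive family
#'   history.
#' @param age_range inclusive `[min, max]` age range in years.
#' @param divergence Balding-Nichols Fst-like divergence between ancestral
#'   and superpopulation allele frequencies, in `[0, 1)`. 0 makes all
#'   ancestries share identical frequencies.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output from every generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1997L,
                       case_fraction = 0.255,
                       n_variants = 1000L,
                       ancestry_labels = SUPERPOPS,
                       dirichlet_alpha = c(AFR = 0.3, AMR = 7.5, EAS = 0.1,
                                           EUR = 2.0, SAS = 0.1),
                       true_or_per_sd = 1.56,
                       covariate_effects = list(
                         density = c(A = 0, B = 0.617, C = 1.652, D = 2.413),
                         family_history = log(2)
                       ),
                       density_probs = c(A = 0.203, B = 0.582, C = 0.194,
                                         D = 0.021),
                       family_history_prob = 0.12,
                       age_range = c(40, 80),
                       divergence = 0.15,
                       seed = 1L) {
  stop_if(!is_count(n_individuals), "n_individuals must be a positive integer")
  stop_if(!is_prob(case_fraction), "case_fraction must lie strictly in (0, 1)")
  stop_if(!is_count(n_variants), "n_variants must be >= 1")
  stop_if(length(ancestry_labels) < 1, "at least one ancestry label required")
  stop_if(anyDuplicated(ancestry_labels) > 0, "duplicate ancestry labels")
  stop_if(length(dirichlet_alpha) != length(ancestry_labels),
          "dirichlet_alpha must have one entry per ancestry")
  stop_if(any(!is.finite(dirichlet_alpha)) || any(dirichlet_alpha <= 0),
          "dirichlet_alpha must be strictly positive")
  stop_if(!is.numeric(true_or_per_sd) || true_or_per_sd <= 0,
          "true_or_per_sd must be positive")
  stop_if(!is.numeric(divergence) || divergence < 0 || divergence >= 1,
          "divergence must lie in [0, 1)")
  stop_if(abs(sum(density_probs) - 1) > 1e-8,
          "density_probs must sum to 1")
  stop_if(!is_prob(family_history_prob),
          "family_history_prob must lie in (0, 1)")
  stop_if(length(age_range) != 2 || age_range[1] > age_range[2],
          "age_range must be [min, max] with min <= max")
  names(dirichlet_alpha) <- ancestry_labels
  structure(
    list(n_individuals = as.integer(n_individuals),
         case_fraction = case_fraction,
         n_variants = as.integer(n_variants),
         ancestry_labels = ancestry_labels,
         dirichlet_alpha = dirichlet_alpha,
         true_or_per_sd = true_or_per_sd,
         covariate_effects = covariate_effects,
         density_probs = density_probs,
         family_history_prob = family_history_prob,
         age_range = age_range,
         divergence = divergence,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate ancestry-specific reference allele frequencies
#'
#' Draws, for each variant, an ancestral frequency and then one frequency per
#' superpopulation from a Balding-Nichols Beta distribution around it:
#' `f_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with divergence `F`.
#' `F = 0` collapses every ancestry onto the shared ancestral frequency.
#' Frequencies are clamped to (0.01, 0.99) so ancestries remain separable but
#' no variant is fixed.
#'
#' @param config a [sim_config()].
#' @return a `ref_frequencies` object: list with `variants` (data frame of
#'   chrom/pos/ref/alt) and `freq` (variants x ancestries matrix).
#' @export
gen_reference_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  K <- length(config$ancestry_labels)
  Fst <- config$divergence
  with_seed(config$seed + 101L, {
    p <- stats::runif(m, 0.05, 0.95)
    if (Fst == 0) {
      freq <- matrix(p, nrow = m, ncol = K)
    } else {
      scale <- (1 - Fst) / Fst
      freq <- vapply(seq_len(K), function(k) {
        stats::rbeta(m, p * scale, (1 - p) * scale)
      }, numeric(m))
    }
    freq <- clamp(freq, 0.01, 0.99)
    colnames(freq) <- config$ancestry_labels
    variants <- data.frame(
      chrom = rep("1", m),
      pos = seq_len(m) * 1000L,
      ref = rep("A", m),
      alt = rep("G", m),
      stringsAsFactors = FALSE
    )
    rownames(freq) <- variant_key(variants$chrom, variants$pos,
                                  variants$ref, variants$alt)
    structure(list(variants = variants, freq = freq),
              class = "ref_frequencies")
  })
}

# Dirichlet draws via normalized gammas
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  q <- g / rowSums(g)
  colnames(q) <- names(alpha)
  q
}

#' Generate an admixed cohort of genotype dosages
#'
#' Each individual receives admixture proportions `q ~ Dirichlet(alpha)` and,
#' independently per variant, a genotype `~ Binomial(2, sum_k q_k f_ik)`
#' where `f_ik` are the ancestry-specific reference frequencies.
#'
#' @param config a [sim_config()].
#' @param ref a `ref_frequencies` object from [gen_reference_frequencies()].
#' @return list with `genotypes` (a [dosage_matrix()]) and `ancestry`
#'   (individuals x ancestries matrix of true admixture proportions,
#'   rows on the simplex).
#' @export
gen_admixed_cohort <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "ref_frequencies"))
  n <- config$n_individuals
  with_seed(config$seed + 202L, {
    q <- rdirichlet(n, config$dirichlet_alpha)
    p <- q %*% t(ref$freq)           # n x m expected allele frequency
    x <- matrix(stats::rbinom(length(p), 2L, p), nrow = n)
    ids <- sprintf("S%05d", seq_len(n))
    rownames(q) <- ids
    list(
      genotypes = dosage_matrix(x, ref$variants, ids),
      ancestry = q
    )
  })
}

# Solve the logistic intercept so the marginal case rate matches target.
solve_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, lower = -40, upper = 40, tol = 1e-6)$root
}

#' Generate covariates (BI-RADS density, family history, age)
#'
#' Base distributions are case-status independent; covariates influence case
#' status only through the logistic outcome model, so marginal
#' case-covariate associations are fully attributable to the configured
#' effects.
#'
#' @param config a [sim_config()].
#' @return data frame with `id`, `age`, `density`, `family_history`.
#' @export
gen_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  with_seed(config$seed + 303L, {
    data.frame(
      id = sprintf("S%05d", seq_len(n)),
      age = sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE),
      density = sample(names(config$density_probs), n, replace = TRUE,
                       prob = config$density_probs),
      family_history = stats::rbinom(n, 1L, config$family_history_prob),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate case-control outcomes from standardized scores
#'
#' Case status is Bernoulli with
#' `P(case | z, F) = logistic(a0 + log(OR_sd) z + covariate effects)`,
#' where the intercept `a0` is solved by 1-D root finding (tolerance 1e-6)
#' so the marginal case rate equals `case_fraction`. At a 25% case fraction
#' the rare-disease approximation would be badly off, hence the exact solve.
#'
#' @param prs_z numeric vector of standardized scores.
#' @param config a [sim_config()].
#' @param covariates optional data frame from [gen_covariates()] with
#'   `density` and `family_history`; omit for a PRS-only outcome model.
#' @return integer vector of case status (1 case, 0 control) with the solved
#'   intercept in attribute `"intercept"`.
#' @export
gen_outcomes <- function(prs_z, config, covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stop_if(any(!is.finite(prs_z)), "prs_z must be finite")
  eta <- log(config$true_or_per_sd) * prs_z
  if (!is.null(covariates)) {
    eff <- config$covariate_effects
    stop_if(!all(covariates$density %in% names(eff$density)),
            "covariate density levels outside configured effects")
    eta <- eta + unname(eff$density[covariates$density]) +
      eff$family_history * covariates$family_history
  }
  a0 <- solve_intercept(eta, config$case_fraction)
  with_seed(config$seed + 404L, {
    y <- stats::rbinom(length(eta), 1L, stats::plogis(a0 + eta))
    attr(y, "intercept") <- a0
    y
  })
}

#' Generate a regional life table
#'
#' Breast-cancer incidence follows a smooth unimodal (Gaussian-in-age) curve
#' peaking near `peak_age`; other-cause mortality is Gompertz (monotone
#' increasing). Defaults emulate a Colombian urban region: peak age-specific
#' incidence of 0.2% per year in the mid 60s and female all-other-cause
#' mortality of about 0.3% per year at age 50 doubling roughly every 8
#' years, which places the peak of the 10-year risk curve near age 60.
#'
#' @param region region name recorded in the table.
#' @param ages contiguous integer age grid.
#' @param peak_age age of maximal incidence.
#' @param peak_incidence annual incidence probability at the peak.
#' @param incidence_width Gaussian width (years) of the incidence curve.
#' @param mortality_at_50 annual other-cause mortality at age 50.
#' @param mortality_log_slope Gompertz log-slope per year of age.
#' @return a `life_table` data frame with columns `region`, `age`,
#'   `incidence`, `mortality_other`.
#' @export
gen_life_table <- function(region = "synthetic",
                           ages = 30:90,
                           peak_age = 65,
                           peak_incidence = 0.002,
                           incidence_width = 12,
                           mortality_at_50 = 0.003,
                           mortality_log_slope = 0.09) {
  stop_if(any(diff(ages) != 1L), "ages must be contiguous integers")
  stop_if(peak_incidence < 0, "peak_incidence must be >= 0")
  inc <- peak_incidence * exp(-0.5 * ((ages - peak_age) / incidence_width)^2)
  mort <- mortality_at_50 * exp(mortality_log_slope * (ages - 50))
  stop_if(any(inc >= 1) || any(mort >= 1),
          "life-table rates must lie in [0, 1)")
  life_table(region = region, age = as.integer(ages),
             incidence = inc, mortality_other = mort)
}

#' Generate an ancestry-tagged PRS scoring panel
#'
#' Draws normal effect weights for a random causal subset of the reference
#' variants and populates the panel's reference mean and SD by scoring a
#' simulated reference cohort of individuals drawn purely from the panel's
#' tagged ancestry, so standardizing that population gives mean 0, SD 1.
#'
#' @param ref a `ref_frequencies` object.
#' @param ancestry superpopulation tag of the panel (must be a column of
#'   `ref$freq`).
#' @param n_causal number of variants with nonzero weight.
#' @param beta_sd standard deviation of the normal effect weights.
#' @param log_or_per_sd per-SD log odds ratio stored on the panel.
#' @param n_reference size of the simulated reference cohort used to fill
#'   the reference mean/SD.
#' @param seed integer seed.
#' @return a [scoring_panel()].
#' @export
gen_scoring_panel <- function(ref, ancestry, n_causal, beta_sd = 0.1,
                              log_or_per_sd = log(1.56),
                              n_reference = 5000L, seed = 1L) {
  stopifnot(inherits(ref, "ref_frequencies"))
  m <- nrow(ref$variants)
  stop_if(n_causal > m, "n_causal exceeds the number of reference variants")
  stop_if(!ancestry %in% colnames(ref$freq),
          "ancestry not present in the reference frequencies")
  with_seed(seed, {
    idx <- sort(sample.int(m, n_causal))
    beta <- stats::rnorm(n_causal, 0, beta_sd)
    v <- ref$variants[idx, , drop = FALSE]
    f <- ref$freq[idx, ancestry]
    # score a pure-ancestry reference cohort to anchor mean/SD
    xr <- matrix(stats::rbinom(n_reference * n_causal, 2L,
                               rep(f, each = n_reference)),
                 nrow = n_reference)
    raw <- as.numeric(xr %*% beta)
    scoring_panel(
      panel_id = paste0("syn_", ancestry),
      ancestry = ancestry,
      variants = data.frame(
        chrom = v$chrom, pos = v$pos,
        effect_allele = v$alt, other_allele = v$ref,
        effect_weight = beta,
        allele_frequency = f,
        stringsAsFactors = FALSE
      ),
      ref_mean = mean(raw),
      # a degenerate (all-zero-weight) panel scores everyone at the mean;
      # unit scale keeps standardization defined with z identically 0
      ref_sd = if (stats::sd(raw) > 0) stats::sd(raw) else 1,
      log_or_per_sd = log_or_per_sd
    )
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining the generators: reference frequencies,
#' admixed cohort, one scoring panel per ancestry, covariates, a PRS built
#' from the panels (ancestry-weighted), outcomes under the logistic model,
#' and a life table.
#'
#' @param config a [sim_config()].
#' @param n_causal causal variants per panel.
#' @param beta_sd effect-weight SD per panel.
#' @return list with `config`, `ref`, `genotypes`, `ancestry` (true
#'   proportions), `panels`, `phenotypes` (id, age, case, family_history,
#'   density), `scores` (per-panel z and combined z), `life_table`.
#' @export
gen_study <- function(config = sim_config(), n_causal = NULL, beta_sd = 0.1) {
  ref <- gen_reference_frequencies(config)
  cohort <- gen_admixed_cohort(config, ref)
  n_causal <- n_causal %||% max(10L, config$n_variants %/% 3L)
  panels <- lapply(seq_along(config$ancestry_labels), function(k) {
    gen_scoring_panel(ref, config$ancestry_labels[k], n_causal,
                      beta_sd = beta_sd, seed = config$seed + 500L + k)
  })
  names(panels) <- config$ancestry_labels
  z <- vapply(panels, function(p) {
    h <- harmonize_panel(p, cohort$genotypes)$panel
    standardize_score(score_prs(cohort$genotypes, h), p)$z
  }, numeric(config$n_individuals))
  comb <- combine_scores(z, cohort$ancestry)
  covs <- gen_covariates(config)
  y <- gen_outcomes(comb$z, config, covs)
  phen <- data.frame(id = covs$id, age = covs$age, case = as.integer(y),
                     family_history = covs$family_history,
                     density = covs$density, stringsAsFactors = FALSE)
  list(config = config, ref = ref, genotypes = cohort$genotypes,
       ancestry = cohort$ancestry, panels = panels, phenotypes = phen,
       scores = data.frame(id = covs$id, z, combined = comb$z,
                           check.names = FALSE),
       life_table = gen_life_table())
}
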