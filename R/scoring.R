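# PRS scoring: raw additive scores per panel, standardization against the
# panel's reference distribution, and the ancestry-proportion-weighted
# combined score.

#' Score a harmonized panel on a genotype matrix
#'
#' Raw PRS per individual: `sum_i beta_i x_i`, where allele-swapped rows
#' contribute `beta_i (2 - x_i)`. Missing dosages are imputed at the
#' expected dosage: `2 sum_k q_k f_ik` when reference frequencies and an
#' ancestry profile are supplied, else `2 f` from the panel-declared effect
#' allele frequency. Individuals with every dosage missing are flagged
#' unreliable rather than silently scored.
#'
#' @param genotypes a [dosage_matrix()].
#' @param panel a `harmonized_panel` from [harmonize_panel()].
#' @param ref optional `ref_frequencies` for ancestry-aware imputation.
#' @param ancestry optional matrix of admixture proportions (individuals x
#'   ancestries), required with `ref`.
#' @return data frame with `id`, `panel_id`, `value`, `n_scored`,
#'   `n_imputed`, `unreliable`.
#' @export
score_prs <- function(genotypes, panel, ref = NULL, ancestry = NULL) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  if (is.list(panel) && !inherits(panel, "harmonized_panel") &&
      inherits(panel$panel, "harmonized_panel")) panel <- panel$panel
  stopifnot(inherits(panel, "harmonized_panel"))
  v <- panel$variants
  n <- length(genotypes$ids)
  if (nrow(v) == 0) {
    return(data.frame(id = genotypes$ids, panel_id = panel$panel_id,
                      value = 0, n_scored = 0L, n_imputed = 0L,
                      unreliable = TRUE))
  }
  x <- genotypes$dosages[, v$col, drop = FALSE]
  miss <- is.na(x)
  if (any(miss)) {
    if (!is.null(ref) && !is.null(ancestry)) {
      key <- variant_key(v$chrom, v$pos,
                         ifelse(v$flip, v$effect_allele, v$other_allele),
                         ifelse(v$flip, v$other_allele, v$effect_allele))
      fk <- ref$freq[key, , drop = FALSE]
      exp_dose <- 2 * ancestry[, colnames(fk), drop = FALSE] %*% t(fk)
    } else if ("allele_frequency" %in% names(v)) {
      # panel frequency is for the effect allele; convert to alt-allele scale
      f_alt <- ifelse(v$flip, 1 - v$allele_frequency, v$allele_frequency)
      exp_dose <- matrix(2 * f_alt, nrow = n, ncol = nrow(v), byrow = TRUE)
    } else {
      stop("missing dosages present but no reference or panel allele ",
           "frequencies available for imputation", call. = FALSE)
    }
    x[miss] <- exp_dose[miss]
  }
  # allele swap: contribution beta * (2 - x)
  eff <- sweep(x, 2, v$flip * 2, function(a, b) abs(b - a))
  value <- drop(eff %*% v$effect_weight)
  all_missing <- rowSums(!miss) == 0L
  data.frame(id = genotypes$ids, panel_id = panel$panel_id, value = value,
             n_scored = nrow(v),
             n_imputed = rowSums(miss),
             unreliable = all_missing, stringsAsFactors = FALSE)
}

#' Standardize raw scores against a panel's reference distribution
#'
#' `z = (raw - reference mean) / reference sd`.
#'
#' @param raw data frame from [score_prs()] (or any frame with `id`,
#'   `panel_id`, `value`).
#' @param panel a [scoring_panel()] (or harmonized panel) carrying
#'   `ref_mean` and `ref_sd`.
#' @return data frame with `id`, `panel_id`, `z`.
#' @export
standardize_score <- function(raw, panel) {
  stop_if(!is.finite(panel$ref_sd) || panel$ref_sd <= 0,
          "panel reference sd must be positive")
  data.frame(id = raw$id, panel_id = panel$panel_id,
             z = (raw$value - panel$ref_mean) / panel$ref_sd,
             stringsAsFactors = FALSE)
}

#' Combine ancestry-specific standardized scores
#'
#' The combined PRS is the ancestry-proportion-weighted average of the
#' per-panel standardized scores, `sum_k q_k z_k`, computed on the z scale
#' (raw scores from different panels are on incomparable scales). The
#' weighted average is then re-standardized against the control (or
#' supplied reference) distribution of the combined value so downstream
#' per-SD effect sizes remain per-SD. Ancestries with proportion below
#' `min_weight` and no matching panel have their weight renormalized over
#' the remaining panels; an ancestry above `min_weight` without a panel is
#' an error.
#'
#' @param z matrix of standardized scores (individuals x panels) with
#'   column names naming the panel's ancestry, or a data frame of the same.
#' @param proportions matrix of admixture proportions (individuals x
#'   ancestries).
#' @param controls optional logical/index vector selecting the individuals
#'   (typically controls) against which the combined value is
#'   re-standardized; default all individuals.
#' @param reference optional numeric vector of combined values from an
#'   external reference; overrides `controls`.
#' @param min_weight ancestry proportion below which a missing panel is
#'   tolerated (default 0.01).
#' @return list with `z` (re-standardized combined score), `raw_combined`
#'   (the weighted average before re-standardization), `center`, `scale`.
#' @export
combine_scores <- function(z, proportions, controls = NULL,
                           reference = NULL, min_weight = 0.01) {
  z <- as.matrix(z)
  q <- as.matrix(proportions)
  stop_if(nrow(z) != nrow(q), "score and proportion rows must align")
  panels <- colnames(z)
  missing_panels <- setdiff(colnames(q), panels)
  if (length(missing_panels) > 0) {
    over <- apply(q[, missing_panels, drop = FALSE], 2, max)
    stop_if(any(over >= min_weight),
            "no panel for ancestry with proportion >= min_weight: ",
            paste(missing_panels[over >= min_weight], collapse = ", "))
  }
  qq <- q[, panels, drop = FALSE]
  w <- qq / rowSums(qq)      # renormalize over ancestries that have a panel
  raw <- rowSums(w * z)
  refv <- if (!is.null(reference)) reference
  else if (!is.null(controls)) raw[controls]
  else raw
  ctr <- mean(refv)
  scl <- stats::sd(refv)
  stop_if(!is.finite(scl) || scl <= 0,
          "degenerate reference for re-standardization")
  list(z = (raw - ctr) / scl, raw_combined = raw, center = ctr, scale = scl)
}
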