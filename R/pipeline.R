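# End-to-end orchestration: simulate -> write artifacts -> read back ->
# ancestry -> score -> fit -> risk -> stratify -> reclassify. Stages hand
# data to one another only through plain files (VCF/TSV/CSV/JSON), so each
# stage is inspectable and restartable, and the synthetic and real input
# paths are identical.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in every output.
#' @param sim a [sim_config()] describing the synthetic study (ignored when
#'   real input paths are supplied in a future extension).
#' @param n_causal causal variants per scoring panel.
#' @param strata a [strata_definition()].
#' @param screening_age guideline screening age.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = NULL, n_causal = NULL,
                       strata = strata_definition(), screening_age = 50) {
  sim <- sim %||% sim_config(n_individuals = 600L, n_variants = 300L,
                             seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 n_causal = n_causal, strata = strata,
                 screening_age = screening_age),
            class = "run_config")
}

log_stage <- function(log, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "")
  c(log, msg)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic admixed case-control study, writes every input
#' artifact (dosage VCF, per-ancestry scoring panels, reference-frequency
#' TSV, phenotype CSV, life-table CSV), re-reads them through the standard
#' readers, estimates admixture proportions, scores and combines the PRS,
#' fits the covariate-only and covariate+PRS logistic models, computes
#' relative risk, 10-year absolute risk and risk-equivalent screening age
#' per individual, assigns risk strata under both models, and quantifies
#' reclassification (NRI, IDI). All outputs land under `config$out_dir`
#' with a metrics JSON carrying the seed; a rerun with the same config
#' reproduces the metrics exactly.
#'
#' @param config a [run_config()].
#' @return list with `metrics` (named list, also written to
#'   `metrics.json`), `files` (paths of written artifacts), `log`
#'   (per-stage record counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  log <- character()

  # -- simulate ------------------------------------------------------------
  study <- gen_study(config$sim, n_causal = config$n_causal)
  log <- log_stage(log, "simulate: %d individuals, %d variants, %d cases",
                   config$sim$n_individuals, config$sim$n_variants,
                   sum(study$phenotypes$case))
  files <- list(
    vcf = write_vcf_dosages(study$genotypes, path("genotypes.vcf")),
    ref = write_ref_frequencies_tsv(study$ref, path("ref_frequencies.tsv")),
    phenotypes = write_phenotypes_csv(study$phenotypes,
                                      path("phenotypes.csv")),
    life = write_life_table_csv(study$life_table, path("life_table.csv"))
  )
  for (a in names(study$panels)) {
    files[[paste0("panel_", a)]] <-
      write_panel_tsv(study$panels[[a]], path(sprintf("panel_%s.tsv", a)))
  }

  # -- read back through the standard readers ------------------------------
  geno <- read_vcf_dosages(files$vcf)
  ref <- read_ref_frequencies_tsv(files$ref)
  phen <- read_phenotypes_csv(files$phenotypes)
  life <- read_life_table_csv(files$life)
  panels <- lapply(names(study$panels), function(a)
    read_panel_tsv(files[[paste0("panel_", a)]]))
  names(panels) <- names(study$panels)
  log <- log_stage(log, "read: %d individuals x %d variants from VCF",
                   length(geno$ids), nrow(geno$variants))

  # -- ancestry ------------------------------------------------------------
  qhat <- estimate_admixture_cohort(geno, ref)
  utils::write.csv(data.frame(id = rownames(qhat), qhat,
                              major = major_ancestry(qhat)),
                   path("ancestry.csv"), row.names = FALSE, quote = FALSE)
  files$ancestry <- path("ancestry.csv")
  log <- log_stage(log, "ancestry: mean estimated proportions %s",
                   paste(sprintf("%s=%.2f", colnames(qhat),
                                 colMeans(qhat)), collapse = " "))

  # -- score ---------------------------------------------------------------
  zmat <- vapply(panels, function(p) {
    h <- harmonize_panel(p, geno)
    log <<- log_stage(log, "harmonize %s: %d/%d matched (%d swapped)",
                      p$panel_id, h$report$n_matched, h$report$n_panel,
                      h$report$n_swapped)
    standardize_score(score_prs(geno, h$panel, ref, qhat), p)$z
  }, numeric(length(geno$ids)))
  controls <- phen$case == 0
  comb <- combine_scores(zmat, qhat, controls = controls)
  scores <- data.frame(id = geno$ids, zmat, combined = comb$z,
                       check.names = FALSE)
  utils::write.csv(scores, path("scores.csv"), row.names = FALSE,
                   quote = FALSE)
  files$scores <- path("scores.csv")

  # -- fit -----------------------------------------------------------------
  dat <- merge(phen, data.frame(id = geno$ids, prs_z = comb$z), by = "id")
  fit0 <- fit_logistic(dat, outcome = "case",
                       predictors = c("age", "density", "family_history"),
                       prs_term = NULL)
  fit1 <- fit_logistic(dat, outcome = "case",
                       predictors = c("prs_z", "age", "density",
                                      "family_history"),
                       prs_term = "prs_z")
  dauc <- auc_increment(fit0, fit1, n_boot = 500L, seed = config$seed)
  log <- log_stage(log,
                   "fit: OR/SD %.3f (%.3f-%.3f), AUC %.3f -> %.3f",
                   fit1$or_per_sd["or"], fit1$or_per_sd["ci_lo"],
                   fit1$or_per_sd["ci_hi"], fit0$auc, fit1$auc)

  # -- risk ----------------------------------------------------------------
  b <- vapply(panels, function(p) p$log_or_per_sd, numeric(1))
  rr_panel <- exp(sweep(zmat, 2, b, `*`))
  rr <- combine_relative_risk(rr_panel, qhat)
  b_comb <- panels[[1]]$log_or_per_sd  # shared per-SD effect across panels
  risk_rows <- lapply(seq_along(geno$ids), function(i) {
    tr <- ten_year_risk(comb$z[i], log_or_per_sd = b_comb, life = life,
                        age = 50)
    ea <- risk_equivalent_age(comb$z[i], log_or_per_sd = b_comb,
                              life = life,
                              reference_age = config$screening_age)
    c(rr = rr[i], ten_year_risk_at_50 = tr$risk, equivalent_age = ea$age)
  })
  risk_df <- data.frame(id = geno$ids, do.call(rbind, risk_rows))
  utils::write.csv(risk_df, path("risk.csv"), row.names = FALSE,
                   quote = FALSE)
  files$risk <- path("risk.csv")

  # -- stratify + reclassify ----------------------------------------------
  # fixed probability cut points (control percentiles of the baseline
  # model) applied to both models, so controls can genuinely move down
  k <- length(config$strata$breaks)
  cuts <- stats::quantile(fit0$fitted[controls],
                          config$strata$breaks[2:(k - 1)])
  bin_prob <- function(p) factor(
    config$strata$labels[findInterval(p, c(-Inf, cuts, Inf))],
    levels = config$strata$labels)
  s_old <- bin_prob(fit0$fitted)
  s_new <- bin_prob(fit1$fitted)
  recl <- nri(s_old, s_new, dat$case)
  idi_val <- idi(fit0$fitted, fit1$fitted, dat$case)
  shifts <- screening_shift_summary(
    risk_df$equivalent_age, assign_strata(comb$z, config$strata),
    diagnosis_age = ifelse(dat$case == 1, dat$age, NA),
    case = dat$case, cutoff = config$screening_age)
  log <- log_stage(log, "reclassify: NRI %.3f (cases %.1f%% up), IDI %.4f",
                   recl$nri, 100 * recl$case_up, idi_val)

  metrics <- list(
    seed = config$seed,
    n_individuals = config$sim$n_individuals,
    n_cases = sum(dat$case),
    case_fraction = mean(dat$case),
    or_per_sd = unname(fit1$or_per_sd["or"]),
    or_per_sd_ci = unname(fit1$or_per_sd[c("ci_lo", "ci_hi")]),
    auc_covariates = fit0$auc,
    auc_with_prs = fit1$auc,
    auc_increment = dauc$delta,
    nri = recl$nri,
    nri_case_up = recl$case_up,
    nri_control_down = recl$control_down,
    idi = idi_val,
    mean_equivalent_age_shift = mean(risk_df$equivalent_age) -
      config$screening_age
  )
  jsonlite::write_json(metrics, path("metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  files$metrics <- path("metrics.json")
  writeLines(log, path("run.log"))
  list(metrics = metrics, files = files, log = log)
}
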