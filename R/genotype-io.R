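# Containers and file IO for the formats the pipeline touches: dosage VCF,
# scoring-panel TSV (PGS-Catalog harmonized column names accepted), phenotype
# CSV, life-table CSV, reference-frequency TSV and PC-loading TSV. All
# coordinates are 1-based (VCF convention).

#' Genotype dosage matrix
#'
#' Individuals x variants matrix of alternate-allele dosages in `[0, 2]`
#' (`NA` marks missing), keyed by `(chrom, pos, ref, alt)`. Multiallelic
#' sites are represented as one column per alternate allele.
#'
#' @param dosages numeric matrix, individuals in rows.
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param ids character vector of individual ids.
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants, ids) {
  dosages <- as.matrix(dosages)
  stop_if(nrow(dosages) != length(ids), "ids do not match dosage rows")
  stop_if(ncol(dosages) != nrow(variants),
          "variants do not match dosage columns")
  stop_if(any(dosages < 0 | dosages > 2, na.rm = TRUE),
          "dosages must lie in [0, 2] or be NA")
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  stop_if(anyDuplicated(keys) > 0, "duplicate variant keys")
  dimnames(dosages) <- list(ids, keys)
  structure(list(ids = as.character(ids),
                 variants = as.data.frame(variants),
                 dosages = dosages),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d individuals x %d variants (%d missing)\n",
              length(x$ids), nrow(x$variants), sum(is.na(x$dosages))))
  invisible(x)
}

#' PRS scoring panel
#'
#' Variant-level effect weights (log odds ratios) for one ancestry-tagged
#' PRS, together with the reference distribution (mean, SD) used for
#' standardization and the panel's per-SD log odds ratio.
#'
#' @param panel_id panel identifier.
#' @param ancestry superpopulation tag (AFR/AMR/EAS/EUR/SAS).
#' @param variants data frame with `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `effect_weight`, optionally `allele_frequency` (of the
#'   effect allele; used for missing-dosage imputation).
#' @param ref_mean,ref_sd reference raw-score mean and SD (`ref_sd > 0`).
#' @param log_or_per_sd log odds ratio per SD of the standardized score.
#' @return object of class `scoring_panel`.
#' @export
scoring_panel <- function(panel_id, ancestry, variants, ref_mean, ref_sd,
                          log_or_per_sd) {
  need <- c("chrom", "pos", "effect_allele", "other_allele", "effect_weight")
  stop_if(!all(need %in% names(variants)),
          "panel variants need columns: ", paste(need, collapse = ", "))
  stop_if(any(variants$effect_allele == variants$other_allele),
          "effect allele must differ from other allele")
  key <- paste(variants$chrom, variants$pos, variants$effect_allele,
               variants$other_allele)
  stop_if(anyDuplicated(key) > 0, "duplicate panel rows")
  stop_if(!is.finite(ref_sd) || ref_sd <= 0, "reference sd must be positive")
  structure(list(panel_id = panel_id, ancestry = ancestry,
                 variants = as.data.frame(variants),
                 ref_mean = ref_mean, ref_sd = ref_sd,
                 log_or_per_sd = log_or_per_sd),
            class = "scoring_panel")
}

#' Region life table
#'
#' @param region region name.
#' @param age contiguous integer ages.
#' @param incidence annual breast-cancer incidence probabilities.
#' @param mortality_other annual other-cause mortality probabilities.
#' @return data frame of class `life_table`.
#' @export
life_table <- function(region, age, incidence, mortality_other) {
  stop_if(any(diff(age) != 1L), "ages must increase in steps of 1")
  stop_if(any(incidence < 0 | incidence >= 1) ||
            any(mortality_other < 0 | mortality_other >= 1),
          "rates must lie in [0, 1)")
  structure(data.frame(region = region, age = as.integer(age),
                       incidence = incidence,
                       mortality_other = mortality_other),
            class = c("life_table", "data.frame"))
}

# ---- VCF -------------------------------------------------------------------

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate
#' alleles from `GT`; missing genotypes (`./.`) become missing dosages.
#' Multiallelic records contribute one matrix column per alternate allele
#' (for `GT`, the count of that allele; for `DS`, the comma-separated
#' per-allele dosage).
#'
#' @param path VCF file (plain or bgzipped).
#' @param ids optional subset of sample ids to keep.
#' @return a [dosage_matrix()].
#' @export
read_vcf_dosages <- function(path, ids = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, "FORMAT", drop = TRUE]
  has_ds <- grepl("(^|:)DS(:|$)", fmt)
  has_gt <- grepl("(^|:)GT(:|$)", fmt)
  bad <- which(!has_ds & !has_gt)
  stop_if(length(bad) > 0,
          sprintf("record %s:%s has neither DS nor GT",
                  fix[bad[1], "CHROM"], fix[bad[1], "POS"]))
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(ids)) {
    miss <- setdiff(ids, samples)
    stop_if(length(miss) > 0, "samples not in VCF: ",
            paste(miss, collapse = ", "))
    samples <- ids
  }
  ds <- if (any(has_ds))
    tryCatch(vcfR::extract.gt(vcf, element = "DS"),
             error = function(e) NULL) else NULL
  gt <- if (any(has_gt))
    tryCatch(vcfR::extract.gt(vcf, element = "GT"),
             error = function(e) NULL) else NULL
  cols <- list(); meta <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    ds_r <- if (has_ds[r] && !is.null(ds)) ds[r, samples] else NULL
    gt_r <- if (has_gt[r] && !is.null(gt)) gt[r, samples] else NULL
    for (a in seq_along(alts)) {
      if (!is.null(ds_r) && !all(is.na(ds_r))) {
        val <- vapply(strsplit(ds_r, ",", fixed = TRUE), function(v) {
          if (length(v) < a || v[a] %in% c(".", "")) NA_real_
          else as.numeric(v[a])
        }, numeric(1))
      } else {
        val <- vapply(gt_r, function(g) {
          if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
          sum(strsplit(g, "[/|]")[[1]] == as.character(a))
        }, numeric(1), USE.NAMES = FALSE)
      }
      cols[[length(cols) + 1L]] <- val
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[a], stringsAsFactors = FALSE)
    }
  }
  dosage_matrix(do.call(cbind, cols), do.call(rbind, meta), samples)
}

#' Write genotype dosages as a VCF with a DS FORMAT field
#'
#' Each variant key becomes one biallelic record; dosages are written to 4
#' decimal places and missing dosages as `.`.
#'
#' @param x a [dosage_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=DS,Number=A,Type=Float,",
                  "Description=\"Alternate allele dosage\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$ids), collapse = "\t"))
  v <- x$variants
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- x$dosages[, i]
    d <- ifelse(is.na(d), ".", formatC(d, digits = 4, format = "fg"))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            ".", "DS", d), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- Scoring panel TSV -----------------------------------------------------

# PGS-Catalog harmonized header aliases
PANEL_ALIASES <- c(chr_name = "chrom", chr_position = "pos",
                   hm_chr = "chrom", hm_pos = "pos",
                   effect_allele = "effect_allele",
                   other_allele = "other_allele",
                   reference_allele = "other_allele",
                   effect_weight = "effect_weight",
                   allelefrequency_effect = "allele_frequency")

#' Read a scoring panel TSV
#'
#' Columns `chrom`, `pos`, `effect_allele`, `other_allele`, `effect_weight`
#' (PGS-Catalog harmonized names such as `chr_name`/`chr_position` accepted
#' as aliases). Panel metadata (id, ancestry, reference mean/SD, log OR per
#' SD) is read from `#key=value` header comment lines.
#'
#' @param path TSV path.
#' @return a [scoring_panel()].
#' @export
read_panel_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in grep("=", meta_lines, value = TRUE)) {
    kv <- strsplit(sub("^#+\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  nm <- names(tab)
  hit <- nm %in% names(PANEL_ALIASES)
  nm[hit] <- unname(PANEL_ALIASES[nm[hit]])
  names(tab) <- nm
  need <- c("chrom", "pos", "effect_allele", "other_allele", "effect_weight")
  miss <- setdiff(need, nm)
  stop_if(length(miss) > 0, sprintf("%s: missing panel columns: %s", path,
                                    paste(miss, collapse = ", ")))
  scoring_panel(
    panel_id = meta$panel_id %||% basename(path),
    ancestry = meta$ancestry %||% NA_character_,
    variants = tab[, intersect(c(need, "allele_frequency"), names(tab))],
    ref_mean = as.numeric(meta$ref_mean %||% 0),
    ref_sd = as.numeric(meta$ref_sd %||% 1),
    log_or_per_sd = as.numeric(meta$log_or_per_sd %||% NA)
  )
}

#' Write a scoring panel TSV
#'
#' @param panel a [scoring_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "scoring_panel"))
  hdr <- sprintf("#%s=%s",
                 c("panel_id", "ancestry", "ref_mean", "ref_sd",
                   "log_or_per_sd"),
                 c(panel$panel_id, panel$ancestry,
                   format(panel$ref_mean, digits = 17),
                   format(panel$ref_sd, digits = 17),
                   format(panel$log_or_per_sd, digits = 17)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(panel$variants, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- Phenotype CSV ---------------------------------------------------------

#' Read a phenotype CSV
#'
#' Requires columns `id`, `age`, `case`; optional `family_history`
#' (0/1/unknown), `density` (A-D/unknown), further covariates and
#' `PC1..PCl`. Validates ages in `[18, 110]`, case status in `{0, 1}` and
#' density levels, reporting offending line numbers.
#'
#' @param path CSV path.
#' @return a validated data frame.
#' @export
read_phenotypes_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "case")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0, sprintf("%s: missing columns: %s", path,
                                    paste(miss, collapse = ", ")))
  bad <- which(tab$age < 18 | tab$age > 110)
  stop_if(length(bad) > 0,
          sprintf("%s line %d: age %s outside [18, 110]", path,
                  bad[1] + 1L, tab$age[bad[1]]))
  bad <- which(!tab$case %in% c(0L, 1L))
  stop_if(length(bad) > 0,
          sprintf("%s line %d: case status must be 0 or 1", path,
                  bad[1] + 1L))
  if ("density" %in% names(tab)) {
    bad <- which(!tab$density %in% c("A", "B", "C", "D", "unknown"))
    stop_if(length(bad) > 0,
            sprintf("%s line %d: density '%s' not in A-D/unknown", path,
                    bad[1] + 1L, tab$density[bad[1]]))
  }
  tab
}

#' Write a phenotype CSV
#' @param phenotypes data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Life table CSV --------------------------------------------------------

#' Read a life-table CSV (columns region, age, incidence, mortality_other)
#' @param path CSV path.
#' @return a [life_table()].
#' @export
read_life_table_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "age", "incidence", "mortality_other")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0, sprintf("%s: missing columns: %s", path,
                                    paste(miss, collapse = ", ")))
  life_table(tab$region, tab$age, tab$incidence, tab$mortality_other)
}

#' Write a life-table CSV
#' @param life a [life_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_life_table_csv <- function(life, path) {
  stopifnot(inherits(life, "life_table"))
  utils::write.csv(as.data.frame(life), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- Reference frequencies / PC loadings TSV -------------------------------

#' Reference allele frequencies per superpopulation
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param freq matrix (variants x ancestries) of alternate-allele
#'   frequencies with ancestry column names.
#' @return object of class `ref_frequencies`.
#' @export
ref_frequencies <- function(variants, freq) {
  freq <- as.matrix(freq)
  stop_if(nrow(freq) != nrow(variants), "variants and freq must align")
  stop_if(is.null(colnames(freq)), "freq needs ancestry column names")
  stop_if(any(freq < 0 | freq > 1), "frequencies must lie in [0, 1]")
  rownames(freq) <- variant_key(variants$chrom, variants$pos, variants$ref,
                                variants$alt)
  structure(list(variants = as.data.frame(variants), freq = freq),
            class = "ref_frequencies")
}

#' Read reference allele frequencies (variant key columns + one column per
#' superpopulation)
#' @param path TSV with columns chrom, pos, ref, alt and ancestry columns.
#' @return a `ref_frequencies` object.
#' @export
read_ref_frequencies_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  keycols <- c("chrom", "pos", "ref", "alt")
  stop_if(!all(keycols %in% names(tab)), path,
          ": needs columns chrom, pos, ref, alt")
  fcols <- setdiff(names(tab), keycols)
  freq <- as.matrix(tab[, fcols, drop = FALSE])
  rownames(freq) <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  structure(list(variants = tab[, keycols], freq = freq),
            class = "ref_frequencies")
}

#' Write reference allele frequencies as TSV
#' @param ref a `ref_frequencies` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ref_frequencies_tsv <- function(ref, path) {
  tab <- cbind(ref$variants, as.data.frame(ref$freq, row.names = NULL))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- Panel harmonization ---------------------------------------------------

#' Harmonize a scoring panel against a genotype matrix
#'
#' Matches panel rows to genotype variants by `(chrom, pos)`. When the
#' effect allele equals the alternate allele the weight applies to the
#' dosage as is; when it equals the reference allele the contribution is
#' flipped (`beta * (2 - x)`), recorded as a swap. Strand-ambiguous
#' (A/T, C/G) rows are dropped or kept per `ambiguous`. Unmatched rows are
#' reported, never silently dropped.
#'
#' @param panel a [scoring_panel()].
#' @param genotypes a [dosage_matrix()].
#' @param ambiguous `"drop"` (default) or `"keep"`.
#' @return list with `panel` (an aligned `harmonized_panel`: variants plus
#'   `col` genotype column index and `flip` flag) and `report` (counts and
#'   row tables of matched / swapped / ambiguous / unmatched / mismatched).
#' @export
harmonize_panel <- function(panel, genotypes, ambiguous = c("drop", "keep")) {
  stopifnot(inherits(panel, "scoring_panel"),
            inherits(genotypes, "dosage_matrix"))
  ambiguous <- match.arg(ambiguous)
  pv <- panel$variants
  gv <- genotypes$variants
  stop_if(nrow(pv) == 0 || nrow(gv) == 0, "empty panel or genotype matrix")
  amb_pair <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  is_amb <- amb_pair(pv$effect_allele, pv$other_allele)
  gkey <- paste(gv$chrom, gv$pos)
  pkey <- paste(pv$chrom, pv$pos)
  col <- match(pkey, gkey)
  status <- rep("matched", nrow(pv))
  flip <- rep(FALSE, nrow(pv))
  status[is.na(col)] <- "unmatched"
  ok <- !is.na(col)
  same <- ok & pv$effect_allele == gv$alt[col] &
    pv$other_allele == gv$ref[col]
  swap <- ok & pv$effect_allele == gv$ref[col] &
    pv$other_allele == gv$alt[col]
  status[ok & !same & !swap] <- "allele_mismatch"
  flip[swap] <- TRUE
  status[swap] <- "swapped"
  if (ambiguous == "drop")
    status[is_amb & status %in% c("matched", "swapped")] <- "ambiguous"
  keep <- status %in% c("matched", "swapped")
  stop_if(!any(keep), "no panel variants could be matched to the genotypes")
  aligned <- pv[keep, , drop = FALSE]
  aligned$col <- col[keep]
  aligned$flip <- flip[keep]
  hp <- structure(list(panel_id = panel$panel_id, ancestry = panel$ancestry,
                       variants = aligned, ref_mean = panel$ref_mean,
                       ref_sd = panel$ref_sd,
                       log_or_per_sd = panel$log_or_per_sd),
                  class = "harmonized_panel")
  report <- list(
    n_panel = nrow(pv),
    n_matched = sum(keep),
    n_swapped = sum(status == "swapped"),
    n_ambiguous = sum(status == "ambiguous"),
    n_unmatched = sum(status == "unmatched"),
    n_allele_mismatch = sum(status == "allele_mismatch"),
    rows = data.frame(chrom = pv$chrom, pos = pv$pos, status = status,
                      stringsAsFactors = FALSE)
  )
  list(panel = hp, report = report)
}
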