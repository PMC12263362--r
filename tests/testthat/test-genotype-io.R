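write_test_vcf <- function(lines, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=A,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), path)
  path
}

test_that("GT genotypes become allele counts and missing GT becomes NA", {
  p <- write_test_vcf(paste(
    c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
      "0/0", "0/1", "1/1"), collapse = "\t"))
  dm <- read_vcf_dosages(p)
  expect_equal(unname(dm$dosages[, 1]), c(0, 1, 2))
  p2 <- write_test_vcf(paste(
    c("1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
      "./.", "0|1", "1|1"), collapse = "\t"))
  dm2 <- read_vcf_dosages(p2)
  expect_equal(unname(dm2$dosages[, 1]), c(NA, 1, 2))
})

test_that("DS dosages pass through and take precedence over GT", {
  p <- write_test_vcf(paste(
    c("1", "200", ".", "C", "T", ".", "PASS", ".", "GT:DS",
      "0/0:1.37", "0/1:0.5", "1/1:2"), collapse = "\t"))
  dm <- read_vcf_dosages(p)
  expect_equal(unname(dm$dosages[, 1]), c(1.37, 0.5, 2))
})

test_that("multiallelic records yield one column per alternate allele and
          round-trip through the writer", {
  p <- write_test_vcf(paste(
    c("1", "300", ".", "A", "C,T", ".", "PASS", ".", "GT",
      "1/2", "0/1", "2/2"), collapse = "\t"))
  dm <- read_vcf_dosages(p)
  expect_equal(nrow(dm$variants), 2)
  expect_equal(dm$variants$alt, c("C", "T"))
  expect_equal(unname(dm$dosages[, 1]), c(1, 1, 0))  # C counts
  expect_equal(unname(dm$dosages[, 2]), c(1, 0, 2))  # T counts
  # writer emits one biallelic record per alt; re-reading is the identity
  out <- tempfile(fileext = ".vcf")
  write_vcf_dosages(dm, out)
  dm2 <- read_vcf_dosages(out)
  expect_equal(dm2$variants, dm$variants)
  expect_equal(dm2$dosages, dm$dosages)
})

test_that("records with neither DS nor GT raise a format error naming the
          record", {
  p <- write_test_vcf(paste(
    c("7", "400", ".", "A", "G", ".", "PASS", ".", "GQ",
      "30", "40", "50"), collapse = "\t"))
  expect_error(read_vcf_dosages(p), "7:400")
})

test_that("dosage write -> read round trip is the identity", {
  dm <- toy_dosage_matrix(n = 5, m = 8)
  dm$dosages[2, 3] <- NA
  out <- tempfile(fileext = ".vcf")
  write_vcf_dosages(dm, out)
  dm2 <- read_vcf_dosages(out)
  expect_equal(dm2$ids, dm$ids)
  expect_equal(dm2$variants$pos, dm$variants$pos)
  expect_equal(dm2$dosages, dm$dosages)
})

test_that("panel TSV round trips, and PGS-Catalog harmonized headers are
          accepted as aliases", {
  v <- data.frame(chrom = "2", pos = c(10L, 20L), effect_allele = c("G", "A"),
                  other_allele = c("A", "C"), effect_weight = c(0.12, -0.3),
                  allele_frequency = c(0.2, 0.4))
  panel <- scoring_panel("p1", "EUR", v, ref_mean = 1.5, ref_sd = 0.7,
                         log_or_per_sd = log(1.56))
  path <- tempfile(fileext = ".tsv")
  write_panel_tsv(panel, path)
  p2 <- read_panel_tsv(path)
  expect_equal(p2$variants$effect_weight, v$effect_weight)
  expect_equal(p2$ref_mean, 1.5)
  expect_equal(p2$ref_sd, 0.7)
  expect_equal(p2$ancestry, "EUR")

  alias <- tempfile(fileext = ".tsv")
  writeLines(c("#panel_id=alias", "#ref_sd=1",
               "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               "1\t100\tA\tG\t0.5"), alias)
  p3 <- read_panel_tsv(alias)
  expect_equal(p3$variants$chrom, 1)
  expect_equal(p3$variants$effect_weight, 0.5)
})

test_that("phenotype and life-table CSVs validate and round trip", {
  phen <- data.frame(id = c("a", "b"), age = c(45L, 60L), case = c(1L, 0L),
                     family_history = c(1L, 0L), density = c("C", "A"))
  path <- tempfile(fileext = ".csv")
  write_phenotypes_csv(phen, path)
  expect_equal(read_phenotypes_csv(path), phen)

  bad <- phen; bad$age[2] <- 150
  write_phenotypes_csv(bad, path)
  expect_error(read_phenotypes_csv(path), "line 3")

  lt <- toy_life(0.004, 0.01)
  lp <- tempfile(fileext = ".csv")
  write_life_table_csv(lt, lp)
  lt2 <- read_life_table_csv(lp)
  expect_equal(lt2$incidence, lt$incidence)
  expect_equal(lt2$age, lt$age)
  expect_error(life_table("x", c(40, 42), c(0, 0), c(0, 0)), "steps of 1")
  expect_error(life_table("x", 40:41, c(0, 1), c(0, 0)), "rates")
})

test_that("reference frequencies and PC loadings round trip through TSV", {
  ref <- toy_ref_2anc(m = 20)
  path <- tempfile(fileext = ".tsv")
  write_ref_frequencies_tsv(ref, path)
  ref2 <- read_ref_frequencies_tsv(path)
  expect_equal(unname(ref2$freq), unname(ref$freq))

  pl <- pc_loadings(ref$variants[1:5, ], center = seq(0.2, 1, 0.2),
                    loadings = matrix(1:10 / 10, 5, 2))
  lp <- tempfile(fileext = ".tsv")
  write_pc_loadings_tsv(pl, lp)
  pl2 <- read_pc_loadings_tsv(lp)
  expect_equal(unname(pl2$center), unname(pl$center))
  expect_equal(unname(pl2$loadings), unname(pl$loadings))
})

test_that("harmonization keeps, flips, drops and reports panel rows
          correctly", {
  geno <- dosage_matrix(
    matrix(c(0, 1, 2, 2, 1, 0, 1, 1), 2, 4),
    data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L),
               ref = c("A", "A", "A", "A"), alt = c("C", "G", "C", "T")),
    c("i1", "i2"))
  pv <- data.frame(
    chrom = "1",
    pos = c(10L, 20L, 30L, 40L, 50L),
    effect_allele = c("C", "A", "G", "T", "C"),
    other_allele = c("A", "G", "C", "A", "A"),
    effect_weight = c(0.1, 0.2, 0.3, 0.4, 0.5))
  panel <- scoring_panel("p", "EUR", pv, 0, 1, log(1.56))
  h <- harmonize_panel(panel, geno)
  # row 1 direct, row 2 swapped, row 3 allele mismatch (G/C not at pos 30),
  # row 4 ambiguous A/T, row 5 unmatched
  expect_equal(h$report$n_matched, 2)
  expect_equal(h$report$n_swapped, 1)
  expect_equal(h$report$n_ambiguous, 1)
  expect_equal(h$report$n_unmatched, 1)
  expect_equal(h$report$n_allele_mismatch, 1)
  expect_equal(h$panel$variants$flip, c(FALSE, TRUE))
  # swapped contribution is beta * (2 - x)
  s <- score_prs(geno, h$panel)
  expect_equal(s$value, c(0.1 * 0 + 0.2 * (2 - 2), 0.1 * 1 + 0.2 * (2 - 2)))
  # keep-ambiguous policy retains the A/T row
  h2 <- harmonize_panel(panel, geno, ambiguous = "keep")
  expect_equal(h2$report$n_matched, 3)
  # zero matches is a hard error
  far <- scoring_panel("q", "EUR",
                       data.frame(chrom = "9", pos = 1L,
                                  effect_allele = "C", other_allele = "A",
                                  effect_weight = 1), 0, 1, 0)
  expect_error(harmonize_panel(far, geno), "no panel variants")
})

test_that("a panel of 10 with 2 ambiguous rows keeps 8 under drop policy", {
  m <- 10
  geno <- dosage_matrix(
    matrix(1, 1, m),
    data.frame(chrom = "1", pos = seq_len(m), ref = "A",
               alt = c(rep("C", 8), "T", "T")),
    "i1")
  pv <- data.frame(chrom = "1", pos = seq_len(m),
                   effect_allele = c(rep("C", 8), "T", "T"),
                   other_allele = "A", effect_weight = 0.1)
  panel <- scoring_panel("p", "EUR", pv, 0, 1, 0)
  h <- harmonize_panel(panel, geno)
  expect_equal(h$report$n_matched, 8)
  expect_equal(h$report$n_ambiguous, 2)
  expect_equal(sum(h$report$rows$status == "ambiguous"), 2)
})

test_that("scoring is invariant to variant order and to the allele
          representation of panel rows", {
  set.seed(5)
  geno <- toy_dosage_matrix(n = 6, m = 10)
  pv <- data.frame(chrom = "1", pos = 100L * (1:10),
                   effect_allele = "C", other_allele = "A",
                   effect_weight = rnorm(10))
  panel <- scoring_panel("p", "EUR", pv, 0, 1, 0)
  v1 <- score_prs(geno, harmonize_panel(panel, geno)$panel)$value

  perm <- sample(10)
  panel_perm <- scoring_panel("p", "EUR", pv[perm, ], 0, 1, 0)
  expect_equal(score_prs(geno, harmonize_panel(panel_perm, geno)$panel)$value,
               v1)

  # representing rows with effect = ref and negated weight shifts the raw
  # score by -2 sum(beta); standardization against the shifted mean is the
  # identity
  flip_rows <- c(2, 5, 7)
  pv2 <- pv
  pv2$effect_allele[flip_rows] <- "A"
  pv2$other_allele[flip_rows] <- "C"
  pv2$effect_weight[flip_rows] <- -pv$effect_weight[flip_rows]
  shift <- -2 * sum(pv$effect_weight[flip_rows])
  panel2 <- scoring_panel("p", "EUR", pv2, ref_mean = shift, ref_sd = 1,
                          log_or_per_sd = 0)
  raw2 <- score_prs(geno, harmonize_panel(panel2, geno)$panel)
  expect_equal(raw2$value, v1 + shift)
  expect_equal(standardize_score(raw2, panel2)$z, v1)
})

test_that("missing dosages are imputed from ancestry-weighted or
          panel-declared frequencies", {
  geno <- dosage_matrix(
    matrix(c(NA, 1), 2, 1),
    data.frame(chrom = "1", pos = 10L, ref = "A", alt = "C"),
    c("i1", "i2"))
  pv <- data.frame(chrom = "1", pos = 10L, effect_allele = "C",
                   other_allele = "A", effect_weight = 1,
                   allele_frequency = 0.25)
  panel <- scoring_panel("p", "EUR", pv, 0, 1, 0)
  h <- harmonize_panel(panel, geno)$panel
  s <- score_prs(geno, h)
  expect_equal(s$value[1], 2 * 0.25)   # panel frequency fallback
  expect_equal(s$n_imputed, c(1L, 0L))
  expect_true(s$unreliable[1])

  ref <- ref_frequencies(data.frame(chrom = "1", pos = 10L, ref = "A",
                                    alt = "C"),
                         matrix(c(0.1, 0.9), 1, 2,
                                dimnames = list(NULL, c("EUR", "AFR"))))
  q <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
              dimnames = list(c("i1", "i2"), c("EUR", "AFR")))
  s2 <- score_prs(geno, h, ref = ref, ancestry = q)
  expect_equal(s2$value[1], 2 * (0.5 * 0.1 + 0.5 * 0.9))
})
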