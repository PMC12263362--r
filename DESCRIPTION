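Package: admixprs
Title: Ancestry-Weighted Polygenic Risk Scores and Absolute Breast Cancer
    Risk in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for applying ancestry-specific polygenic risk scores
    (PRS) to admixed cohorts: supervised admixture-proportion estimation
    against labelled reference allele frequencies, projection onto
    precomputed principal components, panel harmonization and PRS scoring
    from VCF dosages, ancestry-proportion-weighted combination of
    standardized scores, conversion to relative risk, PRS-category
    incidence recalibration under a population-incidence constraint,
    absolute (competing-risk) 10-year and cumulative risk from regional
    life tables, risk-equivalent screening age, logistic risk models with
    discrimination statistics (odds ratio per standard deviation, stratum
    odds ratios, AUC), percentile risk stratification, and reclassification
    metrics (NRI, IDI). A synthetic-data module generates admixed
    case-control cohorts with the statistical structure the analysis
    assumes, so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
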