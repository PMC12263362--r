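# Shared fixtures, built in code.

# constant-rate life table
toy_life <- function(incidence = 0.01, mortality = 0, ages = 40:80,
                     region = "toy") {
  life_table(region = region, age = ages,
             incidence = rep(incidence, length(ages)),
             mortality_other = rep(mortality, length(ages)))
}

# two-ancestry reference with well-separated frequencies
toy_ref_2anc <- function(m = 5000, seed = 42, labels = c("EUR", "AFR")) {
  set.seed(seed)
  f1 <- runif(m, 0.05, 0.35)
  f2 <- runif(m, 0.65, 0.95)
  ref_frequencies(
    data.frame(chrom = "1", pos = seq_len(m), ref = "A", alt = "G"),
    matrix(c(f1, f2), ncol = 2, dimnames = list(NULL, labels))
  )
}

# simulate one individual's dosages from mixing proportions q over ref
sim_dosages <- function(ref, q, seed = 1) {
  set.seed(seed)
  p <- drop(ref$freq %*% q)
  stats::setNames(rbinom(length(p), 2, p), rownames(ref$freq))
}

# grid-search oracle for the 2-ancestry admixture likelihood (0.01 steps)
admix_grid_oracle <- function(dosages, ref, step = 0.01) {
  keys <- intersect(names(dosages), rownames(ref$freq))
  x <- dosages[keys]
  f <- pmin(pmax(ref$freq[keys, ], 1e-4), 1 - 1e-4)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(q1) {
    p <- q1 * f[, 1] + (1 - q1) * f[, 2]
    sum(x * log(p) + (2 - x) * log(1 - p))
  }, numeric(1))
  grid[which.max(ll)]
}

# dosage matrix with exactly representable dosages
toy_dosage_matrix <- function(n = 4, m = 6, seed = 11) {
  set.seed(seed)
  dosage_matrix(
    matrix(sample(seq(0, 2, by = 0.25), n * m, replace = TRUE), n, m),
    data.frame(chrom = "1", pos = 100L * seq_len(m), ref = "A", alt = "C"),
    sprintf("I%02d", seq_len(n))
  )
}

# build a harmonized panel directly (internal shape, for unit tests of
# scoring arithmetic)
make_harmonized <- function(variants, ref_mean = 0, ref_sd = 1,
                            log_or_per_sd = log(1.56),
                            panel_id = "toy", ancestry = "EUR") {
  structure(list(panel_id = panel_id, ancestry = ancestry,
                 variants = variants, ref_mean = ref_mean, ref_sd = ref_sd,
                 log_or_per_sd = log_or_per_sd),
            class = "harmonized_panel")
}

# Table 2 breast-density contingency counts (cases, controls by BI-RADS A-D)
density_counts <- function() {
  rbind(cases = c(A = 41, B = 218, C = 204, D = 47),
        controls = c(A = 302, B = 866, C = 288, D = 31))
}
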