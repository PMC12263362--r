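# Relative risk from standardized scores, PRS-category incidence
# recalibration under the population-incidence constraint, absolute
# (competing-risk) risk from life tables, and the risk-equivalent screening
# age.

#' Relative risk from a standardized score
#'
#' `RR = exp(z * log_or_per_sd)`: the risk multiplier versus the population
#' average implied by a PRS z-score in an ancestry-matched reference
#' distribution.
#'
#' @param z standardized score(s).
#' @param log_or_per_sd log odds ratio per SD.
#' @return numeric vector of relative risks.
#' @export
relative_risk <- function(z, log_or_per_sd) {
  stop_if(any(!is.finite(z)) || any(!is.finite(log_or_per_sd)),
          "inputs must be finite")
  exp(z * log_or_per_sd)
}

#' Ancestry-weighted combination of per-panel relative risks
#'
#' Arithmetic weighted mean `sum_k q_k RR_k` across the ancestry-specific
#' panels (geometric, i.e. log-scale, averaging available via `scale`).
#'
#' @param rr matrix (individuals x panels) or vector of relative risks.
#' @param proportions matching matrix/vector of ancestry proportions
#'   (rows on the simplex).
#' @param scale `"arithmetic"` (default) or `"log"`.
#' @return numeric vector of combined relative risks.
#' @export
combine_relative_risk <- function(rr, proportions,
                                  scale = c("arithmetic", "log")) {
  scale <- match.arg(scale)
  if (is.null(dim(rr))) rr <- t(as.matrix(rr))
  if (is.null(dim(proportions))) proportions <- t(as.matrix(proportions))
  q <- proportions[, colnames(rr) %||% colnames(proportions), drop = FALSE]
  if (scale == "arithmetic") rowSums(q * rr) else exp(rowSums(q * log(rr)))
}

#' Mean relative risk of a PRS percentile category
#'
#' For a standard-normal standardized score and per-SD log odds ratio `b`,
#' the mean relative risk of the percentile bin `[p_lo, p_hi)` is the
#' truncated-lognormal expectation
#' `exp(b^2 / 2) * (pnorm(z_hi - b) - pnorm(z_lo - b)) / (p_hi - p_lo)`
#' with `z = qnorm(p)`. The full bin `[0, 1)` gives the lognormal mean
#' `exp(b^2 / 2)`.
#'
#' @param p_lo,p_hi percentile bounds, `0 <= p_lo < p_hi <= 1`.
#' @param log_or_per_sd per-SD log odds ratio `b`.
#' @return the category mean relative risk.
#' @export
category_rr <- function(p_lo, p_hi, log_or_per_sd) {
  stop_if(!(p_lo >= 0 && p_hi <= 1 && p_lo < p_hi),
          "need 0 <= p_lo < p_hi <= 1 (non-empty bin)")
  b <- log_or_per_sd
  exp(b^2 / 2) *
    (stats::pnorm(stats::qnorm(p_hi) - b) -
       stats::pnorm(stats::qnorm(p_lo) - b)) / (p_hi - p_lo)
}

#' Build PRS risk categories from percentile breaks
#'
#' @param breaks increasing percentile cut points spanning `[0, 1]`
#'   (e.g. `c(0, 0.3, 0.7, 0.9, 1)`).
#' @param log_or_per_sd per-SD log odds ratio used for the category mean
#'   relative risks.
#' @param labels optional category labels.
#' @return data frame of class `risk_categories` with `label`, `p_lo`,
#'   `p_hi`, `share` (`w_k = p_hi - p_lo`) and `rr` (from [category_rr()]).
#' @export
risk_categories <- function(breaks, log_or_per_sd, labels = NULL) {
  stop_if(breaks[1] != 0 || breaks[length(breaks)] != 1 ||
            any(diff(breaks) <= 0),
          "breaks must increase strictly from 0 to 1")
  k <- length(breaks) - 1L
  lab <- labels %||% paste0("cat", seq_len(k))
  out <- data.frame(
    label = lab,
    p_lo = breaks[-length(breaks)],
    p_hi = breaks[-1],
    share = diff(breaks),
    stringsAsFactors = FALSE
  )
  out$rr <- mapply(category_rr, out$p_lo, out$p_hi,
                   MoreArgs = list(log_or_per_sd = log_or_per_sd))
  structure(out, class = c("risk_categories", "data.frame"))
}

#' Recalibrate age-specific incidence by PRS category
#'
#' Multiplicative incidence-scale recalibration
#' `I_k(t) = I_pop(t) * RR_k / sum_j w_j RR_j`, the standard solution to
#' the constraint that the category-share-weighted incidence equal the
#' population incidence at every age: `sum_k w_k I_k(t) = I_pop(t)` holds
#' exactly.
#'
#' @param life a [life_table()].
#' @param categories a [risk_categories()] data frame (columns `share`,
#'   `rr`; shares must sum to 1).
#' @return a `recalibrated_incidence` object: list with `age`, `incidence`
#'   (ages x categories matrix), `mortality_other`, `categories`.
#' @export
recalibrate_incidence <- function(life, categories) {
  stopifnot(inherits(life, "life_table"))
  stop_if(abs(sum(categories$share) - 1) > 1e-9,
          "category shares must partition [0, 1)")
  stop_if(any(categories$rr <= 0), "category relative risks must be > 0")
  norm <- sum(categories$share * categories$rr)
  inc <- outer(life$incidence, categories$rr / norm)
  if (any(inc >= 1)) {
    bad <- which(inc >= 1, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("recalibrated incidence >= 1 at age %d, category ",
                        "%s: model breakdown"),
                 life$age[bad[1]], categories$label[bad[2]]), call. = FALSE)
  }
  colnames(inc) <- categories$label
  structure(list(age = life$age, incidence = inc,
                 mortality_other = life$mortality_other,
                 categories = categories),
            class = "recalibrated_incidence")
}

# core absolute-risk recursion shared by the public functions
absolute_risk_curve <- function(inc, mort, ages, start_age, horizon) {
  i0 <- match(start_age, ages)
  stop_if(is.na(i0) || start_age + horizon - 1 > ages[length(ages)],
          sprintf("ages [%s, %s] outside the life-table grid", start_age,
                  start_age + horizon))
  idx <- i0:(i0 + horizon - 1L)
  I <- inc[idx]; m <- mort[idx]
  # start-of-interval convention: the first term has P_ND = S = 1
  p_nd <- cumprod(c(1, (1 - m)[-horizon]))
  s <- cumprod(c(1, (1 - I)[-horizon]))
  ar <- cumsum(p_nd * s * I)
  list(age = ages[idx], hazard = I, p_nd = p_nd, survival = s,
       ar = ar)
}

#' Cumulative absolute risk with competing mortality
#'
#' Discrete annual recursion `AR(t) = sum_u P_ND(u) S(u) I(u)` over
#' `u = t0 .. t0 + horizon - 1`, with `P_ND(u) = prod_{v < u} (1 - m(v))`
#' the probability of surviving other causes and
#' `S(u) = prod_{v < u} (1 - I(u))` survival from breast cancer, products
#' over `v in [t0, u)` (start-of-interval convention: the first year's term
#' uses `P_ND = S = 1`).
#'
#' @param inc a `recalibrated_incidence` from [recalibrate_incidence()].
#' @param category category label or index within `inc`.
#' @param start_age first age of the projection.
#' @param horizon number of years.
#' @return an `absolute_risk_curve`: list with `age`, `hazard`, `p_nd`,
#'   `survival` and `ar` (cumulative absolute risk, nondecreasing).
#' @export
cumulative_absolute_risk <- function(inc, category, start_age, horizon) {
  stopifnot(inherits(inc, "recalibrated_incidence"))
  if (is.character(category)) {
    category <- match(category, colnames(inc$incidence))
    stop_if(is.na(category), "unknown category label")
  }
  structure(
    absolute_risk_curve(inc$incidence[, category], inc$mortality_other,
                        inc$age, start_age, horizon),
    class = "absolute_risk_curve")
}

#' Ten-year absolute risk for an individual
#'
#' Composes the chain: standardized score(s) -> per-panel relative risk ->
#' ancestry-weighted combined relative risk -> continuous incidence
#' recalibration -> cumulative absolute risk at a 10-year horizon. In the
#' continuous limit the individual's incidence is
#' `I_pop(t) * RR / E[RR]`, with the same normalizer
#' `E[RR] = sum_k q_k exp(b_k^2 / 2)` over the standard-normal reference as
#' the categorical recalibration, so the population-average constraint is
#' preserved.
#'
#' @param z named vector of per-panel standardized scores (names =
#'   ancestries), or a single scalar when `log_or_per_sd` is scalar.
#'   Ignored when `rr` is supplied.
#' @param proportions named ancestry proportions (ignored for scalar `z`
#'   of length 1 with no names).
#' @param log_or_per_sd per-panel log OR per SD (recycled).
#' @param life a [life_table()].
#' @param age current age (start of the 10-year window).
#' @param horizon years, default 10.
#' @param rr optional relative risk already expressed versus the population
#'   average; `rr = 1` reproduces the population risk exactly (no further
#'   normalization is applied).
#' @return list with `rr` (combined relative risk), `mean_rr` (reference
#'   normalizer), `risk` (absolute risk over the horizon), and `curve`.
#' @export
ten_year_risk <- function(z = NULL, proportions = NULL, log_or_per_sd = NULL,
                          life, age, horizon = 10L, rr = NULL) {
  stopifnot(inherits(life, "life_table"))
  if (is.null(rr)) {
    stop_if(is.null(z) || is.null(log_or_per_sd),
            "supply either rr or z with log_or_per_sd")
    b <- rep_len(log_or_per_sd, length(z))
    rr_panels <- relative_risk(z, b)
    if (length(z) > 1L || !is.null(proportions)) {
      stop_if(is.null(proportions),
              "proportions required for multiple panels")
      q <- proportions[names(z)]
      rr <- sum(q * rr_panels) / sum(q)
      mean_rr <- sum(q * exp(b^2 / 2)) / sum(q)
    } else {
      rr <- rr_panels
      mean_rr <- exp(b^2 / 2)
    }
  } else {
    stop_if(!is.null(z), "supply either rr or z, not both")
    mean_rr <- 1   # rr is already relative to the population average
  }
  inc_i <- life$incidence * rr / mean_rr
  stop_if(any(inc_i >= 1), "individual incidence >= 1: model breakdown")
  curve <- absolute_risk_curve(inc_i, life$mortality_other, life$age,
                               age, horizon)
  list(rr = rr, mean_rr = mean_rr, risk = curve$ar[horizon], curve = curve)
}

# population-average 10-year risk at a given age (RR = 1 individual)
population_ten_year_risk <- function(life, age, horizon = 10L) {
  absolute_risk_curve(life$incidence, life$mortality_other, life$age, age,
                      horizon)$ar[horizon]
}

#' Risk-equivalent screening age
#'
#' The smallest age (linear interpolation between integer ages) at which the
#' individual's 10-year absolute risk reaches the population-average 10-year
#' risk of a `reference_age`-year-old (the guideline screening age; 50 for
#' mammography in Colombia). An individual at the population average
#' (`rr = 1`) maps exactly to `reference_age`. When the threshold is never
#' reached inside the life-table range the range end is returned with
#' `clamped = TRUE`.
#'
#' @param z,proportions,log_or_per_sd,life,horizon,rr as in
#'   [ten_year_risk()].
#' @param reference_age guideline screening age, default 50.
#' @return list with `age`, `clamped`, `threshold` (population 10-year risk
#'   at `reference_age`).
#' @export
risk_equivalent_age <- function(z = NULL, proportions = NULL,
                                log_or_per_sd = NULL, life,
                                reference_age = 50, horizon = 10L,
                                rr = NULL) {
  thr <- population_ten_year_risk(life, reference_age, horizon)
  ages <- life$age[1]:(life$age[length(life$age)] - horizon + 1L)
  risks <- vapply(ages, function(a) {
    ten_year_risk(z, proportions, log_or_per_sd, life, a, horizon,
                  rr = rr)$risk
  }, numeric(1))
  hit <- which(risks >= thr - 1e-15)
  if (length(hit) == 0)
    return(list(age = ages[length(ages)], clamped = TRUE, threshold = thr))
  i <- hit[1]
  if (i == 1L)
    return(list(age = ages[1], clamped = risks[1] > thr + 1e-12,
                threshold = thr))
  # linear interpolation between the bracketing integer ages
  a <- ages[i - 1] + (thr - risks[i - 1]) / (risks[i] - risks[i - 1])
  list(age = a, clamped = FALSE, threshold = thr)
}
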