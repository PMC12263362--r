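# Percentile risk strata, reclassification metrics (NRI, IDI) and the
# screening-age shift summary.

# percentile of each value of x on the scale set by `reference`, with ties
# taking the mean rank: p = (#{ref < x} + 0.5 #{ref = x}) / n_ref
ecdf_percentile <- function(x, reference) {
  vapply(x, function(v) {
    (sum(reference < v) + 0.5 * sum(reference == v)) / length(reference)
  }, numeric(1))
}

#' Risk strata definition on the percentile scale
#'
#' Default four strata: low `[0, 0.30)`, standard `[0.30, 0.70)`, moderate
#' `[0.70, 0.90)`, high `[0.90, 1]`. Bins are left-closed; the top bin is
#' closed at 1.
#'
#' @param breaks strictly increasing cut points from 0 to 1.
#' @param labels stratum labels, one fewer than `breaks`.
#' @return object of class `strata_definition`.
#' @export
strata_definition <- function(breaks = c(0, 0.30, 0.70, 0.90, 1),
                              labels = c("low", "standard", "moderate",
                                         "high")) {
  stop_if(breaks[1] != 0 || breaks[length(breaks)] != 1 ||
            any(diff(breaks) <= 0),
          "breaks must increase strictly from 0 to 1")
  stop_if(length(labels) != length(breaks) - 1L,
          "need one label per stratum")
  structure(list(breaks = breaks, labels = labels),
            class = "strata_definition")
}

#' Assign percentile risk strata
#'
#' Converts scores to percentiles — `pnorm(z)` under the analytic
#' standard-normal reference, or the mean-rank empirical CDF of a reference
#' sample (typically study controls) — and bins them with left-closed
#' intervals (a value exactly at the 30th percentile falls in the standard
#' stratum; the top bin is closed at 1).
#'
#' @param z numeric scores (or probabilities, if `reference` is on that
#'   scale).
#' @param strata a [strata_definition()].
#' @param reference numeric reference sample for empirical percentiles;
#'   `NULL` selects the analytic standard-normal reference.
#' @return factor of stratum labels with attribute `"percentile"`.
#' @export
assign_strata <- function(z, strata = strata_definition(),
                          reference = NULL) {
  stopifnot(inherits(strata, "strata_definition"))
  if (is.null(reference)) {
    p <- stats::pnorm(z)
  } else {
    stop_if(length(unique(reference)) < 2,
            "constant reference: percentiles undefined")
    p <- ecdf_percentile(z, reference)
  }
  bin <- findInterval(p, strata$breaks, rightmost.closed = TRUE)
  out <- factor(strata$labels[bin], levels = strata$labels)
  attr(out, "percentile") <- p
  out
}

#' Net reclassification improvement between two stratum assignments
#'
#' Builds the old x new movement matrix separately for cases and controls
#' and computes the categorical NRI:
#' `(P_up|case - P_down|case) + (P_down|control - P_up|control)`,
#' where "up" means moving to a higher stratum. Components are reported
#' separately alongside the sum.
#'
#' @param old,new stratum assignments as ordered factors sharing levels
#'   (e.g. from [assign_strata()]), lowest risk first; or numeric vectors
#'   binned with `strata`.
#' @param labels binary case status (1 case, 0 control).
#' @param strata optional [strata_definition()] used to bin numeric
#'   `old`/`new` (interpreted as percentile-scale values).
#' @return object of class `reclassification_result`: list with
#'   `matrix_cases`, `matrix_controls`, `case_up`, `case_down`,
#'   `control_up`, `control_down`, `nri_cases`, `nri_controls`, `nri`.
#' @export
nri <- function(old, new, labels, strata = NULL) {
  stop_if(length(old) != length(new) || length(old) != length(labels),
          "old, new and labels must cover the same individuals")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  if (!is.null(strata)) {
    bin <- function(p) factor(
      strata$labels[findInterval(p, strata$breaks, rightmost.closed = TRUE)],
      levels = strata$labels)
    old <- bin(old); new <- bin(new)
  }
  stop_if(!identical(levels(old), levels(new)),
          "old and new strata must share levels")
  io <- as.integer(old); in_ <- as.integer(new)
  lv <- levels(old)
  tab <- function(sel) table(factor(lv[io[sel]], lv),
                             factor(lv[in_[sel]], lv),
                             dnn = c("old", "new"))
  cases <- labels == 1
  up <- in_ > io; down <- in_ < io
  case_up <- mean(up[cases]); case_down <- mean(down[cases])
  ctrl_up <- mean(up[!cases]); ctrl_down <- mean(down[!cases])
  structure(list(
    matrix_cases = tab(cases), matrix_controls = tab(!cases),
    case_up = case_up, case_down = case_down,
    control_up = ctrl_up, control_down = ctrl_down,
    nri_cases = case_up - case_down,
    nri_controls = ctrl_down - ctrl_up,
    nri = (case_up - case_down) + (ctrl_down - ctrl_up)
  ), class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf(paste0("<reclassification_result> NRI = %.4f ",
                     "(cases %.4f: %.1f%% up, %.1f%% down; ",
                     "controls %.4f: %.1f%% down, %.1f%% up)\n"),
              x$nri, x$nri_cases, 100 * x$case_up, 100 * x$case_down,
              x$nri_controls, 100 * x$control_down, 100 * x$control_up))
  invisible(x)
}

#' Integrated discrimination improvement
#'
#' `(mean p_new|case - mean p_old|case) -
#'  (mean p_new|control - mean p_old|control)`: the change in the
#' discrimination slope between two models' predicted probabilities.
#'
#' @param p_old,p_new predicted probabilities in `[0, 1]` from the old and
#'   new model, same individuals.
#' @param labels binary case status.
#' @return the IDI.
#' @export
idi <- function(p_old, p_new, labels) {
  stop_if(any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1),
          "probabilities must lie in [0, 1]")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  cases <- labels == 1
  (mean(p_new[cases]) - mean(p_old[cases])) -
    (mean(p_new[!cases]) - mean(p_old[!cases]))
}

#' Summarize screening-age shifts by risk stratum
#'
#' Per-stratum mean shift of the risk-equivalent screening age relative to
#' the guideline age, and — among cases diagnosed before the guideline age —
#' the count and fraction whose equivalent age precedes their diagnosis age
#' (i.e. who would have been screening-eligible before diagnosis).
#'
#' @param equivalent_age per-individual risk-equivalent screening ages.
#' @param stratum factor of risk strata.
#' @param diagnosis_age diagnosis ages (NA for controls).
#' @param case binary case status.
#' @param cutoff guideline screening age, default 50.
#' @return list with `by_stratum` (data frame: stratum, n, mean_shift —
#'   negative = eligible earlier than the guideline age) and
#'   `early_cases` (n_under_cutoff, n_earlier, fraction_earlier).
#' @export
screening_shift_summary <- function(equivalent_age, stratum, diagnosis_age,
                                    case, cutoff = 50) {
  shift <- equivalent_age - cutoff
  by_str <- data.frame(
    stratum = levels(stratum),
    n = as.integer(table(stratum)[levels(stratum)]),
    mean_shift = as.numeric(tapply(shift, stratum, mean)[levels(stratum)]),
    stringsAsFactors = FALSE
  )
  early <- case == 1 & !is.na(diagnosis_age) & diagnosis_age < cutoff
  n_early <- sum(early)
  n_flag <- sum(equivalent_age[early] < diagnosis_age[early])
  list(by_stratum = by_str,
       early_cases = list(
         n_under_cutoff = n_early,
         n_earlier = n_flag,
         fraction_earlier = if (n_early > 0) n_flag / n_early else NA_real_))
}
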