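# Logistic risk models and discrimination statistics: OR per SD, stratum
# odds ratios versus the central quintile, AUC (tie-corrected concordance),
# AUC increments, and contingency-table tests.

# factor with an explicit "unknown" level rather than row deletion, so n is
# preserved when covariate levels are missing
as_model_factor <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  factor(x, levels = unique(c(setdiff(sort(unique(x)), "unknown"),
                              if ("unknown" %in% x) "unknown")))
}

#' Fit a logistic risk model
#'
#' Fits `outcome ~ predictors` by iteratively reweighted least squares
#' (via [stats::glm()]) with Wald confidence intervals on the log-odds
#' scale, exponentiated. Character/factor predictors enter with an explicit
#' `"unknown"` level instead of row deletion. Separation and
#' non-convergence raise explicit errors.
#'
#' @param data data frame containing the outcome and predictors.
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of predictor column names; the first
#'   is treated as the PRS term for `or_per_sd` unless `prs_term` is given.
#' @param prs_term name of the standardized-PRS predictor (for the reported
#'   OR per SD); `NULL` if none.
#' @param level confidence level, default 0.95.
#' @return object of class `logistic_fit`: list with `coefficients` (data
#'   frame: estimate, se, or, ci_lo, ci_hi, p), `or_per_sd` (named vector
#'   or, ci_lo, ci_hi for the PRS term), `auc` of the fitted probabilities,
#'   `fitted`, `outcome` (observed), `glm` (the underlying fit).
#' @export
fit_logistic <- function(data, outcome = "case", predictors,
                         prs_term = NULL, level = 0.95) {
  stop_if(!outcome %in% names(data), "outcome column not found")
  y <- data[[outcome]]
  stop_if(!all(y %in% c(0, 1)), "outcome must be binary 0/1")
  stop_if(length(unique(y)) < 2, "need at least one case and one control")
  df <- data.frame(.y = y)
  for (p in predictors) {
    stop_if(!p %in% names(data), "predictor not found: ", p)
    v <- data[[p]]
    df[[p]] <- if (is.numeric(v)) v
    else if (is.factor(v)) v          # caller-chosen level order kept
    else as_model_factor(v)
    stop_if(length(unique(df[[p]])) < 2, "constant predictor: ", p)
  }
  form <- stats::as.formula(paste(".y ~", paste(predictors, collapse = "+")))
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warn_sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  stop_if(!fit$converged, "logistic model did not converge after 100 ",
          "IRLS iterations (deviance ", format(fit$deviance), ")")
  cf <- summary(fit)$coefficients
  stop_if(warn_sep && any(abs(cf[, "Estimate"]) > 12),
          "separation detected: diverging coefficient(s) ",
          paste(rownames(cf)[abs(cf[, "Estimate"]) > 12], collapse = ", "))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    or = exp(cf[, "Estimate"]),
    ci_lo = exp(cf[, "Estimate"] - zq * cf[, "Std. Error"]),
    ci_hi = exp(cf[, "Estimate"] + zq * cf[, "Std. Error"]),
    p = cf[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  prs_term <- prs_term %||% predictors[1]
  orsd <- if (!is.null(prs_term) && prs_term %in% coefs$term) {
    r <- coefs[coefs$term == prs_term, ]
    c(or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi, se_log = r$se)
  } else NULL
  structure(list(coefficients = coefs, or_per_sd = orsd,
                 auc = auc(stats::fitted(fit), y),
                 fitted = stats::fitted(fit), outcome = y, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> AUC =", format(x$auc, digits = 4))
  if (!is.null(x$or_per_sd))
    cat(sprintf(", OR/SD = %.3f (%.3f-%.3f)", x$or_per_sd["or"],
                x$or_per_sd["ci_lo"], x$or_per_sd["ci_hi"]))
  cat("\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Odds ratios for PRS percentile strata versus a reference stratum
#'
#' Assigns each individual to a percentile stratum of the standardized
#' score, then fits a logistic regression with stratum indicators (the
#' reference stratum, by default the central quintile 40-60%, omitted)
#' plus optional adjusters, and reports per-stratum odds ratios with Wald
#' confidence intervals. Empty strata are reported as missing, not zero.
#'
#' @param z standardized scores.
#' @param case binary case status.
#' @param breaks increasing percentile cut points from 0 to 1; default
#'   quintiles with the top quintile split at the 90th percentile.
#' @param reference `c(lo, hi)` percentile bounds of the reference stratum.
#' @param adjusters optional data frame of adjustment covariates.
#' @param percentiles `"analytic"` (standard-normal, `pnorm(z)`) or
#'   `"empirical"` (mean-rank ECDF of `z` itself or of `reference_sample`).
#' @param reference_sample optional numeric vector defining the empirical
#'   percentile scale.
#' @param level confidence level.
#' @return data frame with `stratum`, `p_lo`, `p_hi`, `n_cases`,
#'   `n_controls`, `or`, `ci_lo`, `ci_hi`, `p`; the reference row has
#'   `or = 1` and `NA` intervals.
#' @export
stratum_or <- function(z, case, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 0.9, 1),
                       reference = c(0.4, 0.6), adjusters = NULL,
                       percentiles = c("analytic", "empirical"),
                       reference_sample = NULL, level = 0.95) {
  percentiles <- match.arg(percentiles)
  stop_if(breaks[1] != 0 || breaks[length(breaks)] != 1 ||
            any(diff(breaks) <= 0),
          "breaks must increase strictly from 0 to 1")
  stop_if(!all(reference %in% breaks),
          "reference bounds must be break points")
  p <- if (percentiles == "analytic") stats::pnorm(z)
  else ecdf_percentile(z, reference_sample %||% z)
  bin <- findInterval(p, breaks, rightmost.closed = TRUE)
  k <- length(breaks) - 1L
  lab <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  ref_bin <- which(breaks == reference[1])
  stop_if(breaks[ref_bin + 1] != reference[2],
          "reference must be a single stratum")
  stratum <- factor(bin, levels = c(ref_bin, setdiff(seq_len(k), ref_bin)),
                    labels = lab[c(ref_bin, setdiff(seq_len(k), ref_bin))])
  stop_if(sum(case[bin == ref_bin]) == 0 || sum(1 - case[bin == ref_bin]) == 0,
          "reference stratum lacks cases or controls")
  df <- data.frame(case = case, stratum = stratum)
  preds <- "stratum"
  if (!is.null(adjusters)) {
    df <- cbind(df, adjusters)
    preds <- c(preds, names(adjusters))
  }
  present <- levels(stratum)[table(stratum)[levels(stratum)] > 0]
  df2 <- df[df$stratum %in% present, , drop = FALSE]
  df2$stratum <- droplevels(df2$stratum)
  fit <- fit_logistic(df2, outcome = "case", predictors = preds,
                      prs_term = NULL, level = level)
  cf <- fit$coefficients
  out <- data.frame(stratum = lab,
                    p_lo = breaks[-length(breaks)], p_hi = breaks[-1],
                    n_cases = as.integer(tapply(case, factor(bin, seq_len(k)),
                                                sum, default = 0L)),
                    n_controls = as.integer(
                      tapply(1 - case, factor(bin, seq_len(k)), sum,
                             default = 0L)),
                    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  out$or[ref_bin] <- 1
  for (i in setdiff(seq_len(k), ref_bin)) {
    term <- paste0("stratum", lab[i])
    j <- match(term, cf$term)
    if (!is.na(j)) {
      out$or[i] <- cf$or[j]; out$ci_lo[i] <- cf$ci_lo[j]
      out$ci_hi[i] <- cf$ci_hi[j]; out$p[i] <- cf$p[j]
    }
  }
  out
}

#' Area under the ROC curve (tie-corrected concordance)
#'
#' Mann-Whitney concordance with half credit for ties:
#' `[#(case > control) + 0.5 #(case = control)] / (n1 n0)`, computed from
#' mean ranks. Invariant under strictly monotone transforms of the score.
#'
#' @param score numeric predictor (higher = more case-like).
#' @param labels binary 0/1 outcome.
#' @return the AUC.
#' @export
auc <- function(score, labels) {
  stop_if(length(score) != length(labels), "score/label length mismatch")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  stop_if(n1 == 0 || n0 == 0, "both classes must be present")
  r <- rank(score)   # mean ranks give ties half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC increment between two nested logistic fits
#'
#' `AUC(with) - AUC(without)` on the same individuals, with a seeded
#' bootstrap percentile confidence interval (resampling individuals,
#' recomputing both AUCs from the stored fitted probabilities).
#'
#' @param fit_without,fit_with [fit_logistic()] objects on the same data.
#' @param n_boot bootstrap resamples, default 2000.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level.
#' @return list with `delta`, `ci` (length-2), `auc_without`, `auc_with`.
#' @export
auc_increment <- function(fit_without, fit_with, n_boot = 2000L, seed = 1L,
                          level = 0.95) {
  y <- fit_with$outcome
  stop_if(length(y) != length(fit_without$outcome) ||
            any(y != fit_without$outcome),
          "fits must be on the same data")
  p0 <- fit_without$fitted; p1 <- fit_with$fitted
  delta <- auc(p1, y) - auc(p0, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[i])) < 2) return(NA_real_)
      auc(p1[i], y[i]) - auc(p0[i], y[i])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  list(delta = delta,
       ci = unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE)),
       auc_without = auc(p0, y), auc_with = auc(p1, y))
}

#' Chi-square or Fisher test on a contingency table
#'
#' Pearson chi-square by default; Fisher's exact test for 2x2 tables when
#' requested or when any expected count falls below 5. Zero-margin rows or
#' columns are dropped with a warning.
#'
#' @param counts matrix of nonnegative integer counts.
#' @param method `"auto"` (default), `"chisq"` or `"fisher"`.
#' @return list with `method`, `statistic` (NA for Fisher), `df`,
#'   `p_value`.
#' @export
contingency_tests <- function(counts, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "counts must be nonnegative integers")
  keep_r <- rowSums(counts) > 0; keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns", call. = FALSE)
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  stop_if(nrow(counts) < 2 || ncol(counts) < 2,
          "need at least a 2x2 table after dropping zero margins")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "auto") {
    method <- if (all(dim(counts) == 2) && any(expected < 5)) "fisher"
    else "chisq"
  }
  if (method == "fisher") {
    stop_if(!all(dim(counts) == 2), "Fisher test implemented for 2x2 tables")
    ft <- stats::fisher.test(counts)
    list(method = "fisher", statistic = NA_real_, df = NA_integer_,
         p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(method = "chisq", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
  }
}
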