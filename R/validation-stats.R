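#' Cross-tabulate predictions against gold-standard labels
#'
#' Builds the 2x2 table underlying every diagnostic-accuracy measure:
#' `tp` (predicted positive, label positive), `fp`, `fn`, `tn`, with
#' NSCLC as the positive class by default.
#'
#' @param predictions data.frame with `patient_id`, `predicted`.
#' @param labels data.frame with `patient_id`, `subtype`.
#' @param positive_class positive class (default "NSCLC").
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(predictions, labels, positive_class = "NSCLC") {
  if (!setequal(predictions$patient_id, labels$patient_id) ||
      anyDuplicated(predictions$patient_id) || anyDuplicated(labels$patient_id)) {
    stop_casefindr("predictions and labels must cover the same patients exactly once",
                   class = "casefindr_contract_error")
  }
  pred <- predictions$predicted[match(labels$patient_id, predictions$patient_id)]
  truth <- labels$subtype
  pred_pos <- pred == positive_class
  lab_pos <- truth == positive_class
  confusion_counts(tp = sum(pred_pos & lab_pos),
                   fp = sum(pred_pos & !lab_pos),
                   fn = sum(!pred_pos & lab_pos),
                   tn = sum(!pred_pos & !lab_pos),
                   positive_class = positive_class)
}

#' Construct a confusion table from bare counts
#'
#' Useful for worked examples and for re-analysing published 2x2 tables.
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @param positive_class label of the positive class.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive_class = "NSCLC") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn,
                 positive_class = positive_class),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              label = c("positive", "negative")))
  cat(sprintf("<confusion_table> positive class: %s, N = %d\n",
              x$positive_class, x$total))
  print(m)
  invisible(x)
}

# Wilson score interval for a binomial proportion; behaves sensibly at the
# 0 and 1 boundaries, unlike the Wald interval.
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic odds ratio of a 2x2 table
#'
#' DOR = (tp*tn)/(fp*fn), with a Woolf log-method confidence interval,
#' `exp(log(DOR) +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`. With a zero
#' cell the DOR is undefined; the Haldane–Anscombe correction (add 0.5 to
#' every cell) can be requested explicitly.
#'
#' @param ct a `confusion_table`.
#' @param zero_cell_correction `"none"` (zero cell gives `NA` with a
#'   reason) or `"haldane"`.
#' @param conf_level confidence level for the interval.
#' @return list: `dor`, `ci_low`, `ci_high`, `correction_applied`,
#'   `undefined_reason` (NA unless the DOR could not be computed).
#' @export
diagnostic_odds_ratio <- function(ct, zero_cell_correction = c("none", "haldane"),
                                  conf_level = 0.95) {
  zero_cell_correction <- match.arg(zero_cell_correction)
  cells <- c(ct$tp, ct$fp, ct$fn, ct$tn)
  correction_applied <- FALSE
  if (any(cells == 0)) {
    if (zero_cell_correction == "haldane") {
      cells <- cells + 0.5
      correction_applied <- TRUE
    } else {
      return(list(dor = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  correction_applied = FALSE,
                  undefined_reason = "zero cell and no correction enabled"))
    }
  }
  dor <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(sum(1 / cells))
  list(dor = dor,
       ci_low = exp(log(dor) - z * se_log),
       ci_high = exp(log(dor) + z * se_log),
       correction_applied = correction_applied,
       undefined_reason = NA_character_)
}

#' Diagnostic-accuracy measures of a 2x2 table
#'
#' The full measure set for a dichotomous test against a gold standard:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/N`, diagnostic odds ratio
#' `(tp*tn)/(fp*fn)`, and the binary-test AUC `(Se+Sp)/2` (the area under
#' the single-operating-point ROC). Proportions carry Wilson 95 percent
#' intervals; the DOR a Woolf log-method interval. A measure whose
#' denominator is zero is reported as `NA` and listed in `undefined`.
#'
#' @param ct a `confusion_table`.
#' @param conf_level confidence level.
#' @param dor_zero_cell_correction passed to [diagnostic_odds_ratio()].
#' @return object of class `diagnostic_accuracy`: per-measure `estimate`,
#'   `ci_low`, `ci_high` in a data.frame, plus the source table.
#' @export
accuracy_measures <- function(ct, conf_level = 0.95,
                              dor_zero_cell_correction = "none") {
  stopifnot(inherits(ct, "confusion_table"))
  prop <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, wilson_ci(x, n, conf_level))
  }
  se <- prop(ct$tp, ct$tp + ct$fn)
  sp <- prop(ct$tn, ct$tn + ct$fp)
  ppv <- prop(ct$tp, ct$tp + ct$fp)
  npv <- prop(ct$tn, ct$tn + ct$fn)
  acc <- prop(ct$tp + ct$tn, ct$total)
  dor <- diagnostic_odds_ratio(ct, dor_zero_cell_correction, conf_level)
  auc <- (se[1] + sp[1]) / 2
  # single-operating-point AUC variance: independent Se and Sp binomials
  auc_var <- (se[1] * (1 - se[1]) / (ct$tp + ct$fn) +
                sp[1] * (1 - sp[1]) / (ct$tn + ct$fp)) / 4
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  auc_ci <- c(max(0, auc - z * sqrt(auc_var)), min(1, auc + z * sqrt(auc_var)))

  measures <- data.frame(
    measure = c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                "dor", "auc"),
    estimate = c(se[1], sp[1], ppv[1], npv[1], acc[1], dor$dor, auc),
    ci_low = c(se[2], sp[2], ppv[2], npv[2], acc[2], dor$ci_low, auc_ci[1]),
    ci_high = c(se[3], sp[3], ppv[3], npv[3], acc[3], dor$ci_high, auc_ci[2]),
    stringsAsFactors = FALSE)
  undefined <- measures$measure[is.na(measures$estimate)]
  structure(list(measures = measures, table = ct,
                 conf_level = conf_level,
                 dor_correction_applied = dor$correction_applied,
                 undefined = undefined),
            class = "diagnostic_accuracy")
}

#' Extract one measure from a diagnostic_accuracy object
#' @param da a `diagnostic_accuracy` object.
#' @param measure measure name ("sensitivity", ..., "dor", "auc").
#' @export
da_estimate <- function(da, measure) {
  da$measures$estimate[match(measure, da$measures$measure)]
}

#' @export
print.diagnostic_accuracy <- function(x, digits = 1, ...) {
  cat(sprintf("<diagnostic_accuracy> N = %d (positive class: %s)\n",
              x$table$total, x$table$positive_class))
  m <- x$measures
  for (i in seq_len(nrow(m))) {
    if (m$measure[i] %in% c("dor", "auc")) {
      cat(sprintf("  %-11s %s (95%% CI %s, %s)\n", m$measure[i],
                  format(round(m$estimate[i], 2 + (m$measure[i] == "dor"))),
                  format(round(m$ci_low[i], 2)), format(round(m$ci_high[i], 2))))
    } else {
      cat(sprintf("  %-11s %.*f%% (95%% CI %.*f, %.*f)\n", m$measure[i],
                  digits, 100 * m$estimate[i], digits, 100 * m$ci_low[i],
                  digits, 100 * m$ci_high[i]))
    }
  }
  if (length(x$undefined) > 0L)
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise demographics and cancer features by subtype
#'
#' Reproduces the shape of a standard claims-cohort characteristics table:
#' per-subtype patient counts and percentages, mean, SD and median for the
#' continuous features (age, Deyo–Charlson comorbidity index, BMI), and
#' counts with in-subtype percentages for the categoricals (gender,
#' insurance, region, cancer stage).
#'
#' @param patients patient data.frame.
#' @param labels label data.frame.
#' @return data.frame with columns `feature`, `level`, and one
#'   `<subtype>` column per subtype holding formatted summaries.
#' @export
describe_cohort <- function(patients, labels) {
  df <- merge(patients, labels, by = "patient_id")
  subtypes <- c("SCLC", "NSCLC")
  n_by <- vapply(subtypes, function(s) sum(df$subtype == s), integer(1))
  fmt_n <- function(n, denom) sprintf("%d (%.1f)", n, 100 * n / denom)
  fmt_cont <- function(x) sprintf("%.1f ± %.1f (%.1f)", mean(x, na.rm = TRUE),
                                  stats::sd(x, na.rm = TRUE),
                                  stats::median(x, na.rm = TRUE))
  rows <- list(data.frame(feature = "n", level = "",
                          SCLC = fmt_n(n_by[["SCLC"]], nrow(df)),
                          NSCLC = fmt_n(n_by[["NSCLC"]], nrow(df)),
                          stringsAsFactors = FALSE))
  cont_feats <- c(age = "age_at_index", dci = "dci_score", bmi = "bmi")
  for (f in names(cont_feats)) {
    col <- cont_feats[[f]]
    if (!col %in% names(df)) next
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, level = "mean ± SD (median)",
      SCLC = fmt_cont(df[[col]][df$subtype == "SCLC"]),
      NSCLC = fmt_cont(df[[col]][df$subtype == "NSCLC"]),
      stringsAsFactors = FALSE)
  }
  cat_feats <- c("gender", "insurance", "region", "cancer_stage")
  for (f in cat_feats) {
    if (!f %in% names(df)) next
    levels_f <- if (f == "cancer_stage") STAGES else
      sort(unique(stats::na.omit(df[[f]])))
    for (lv in levels_f) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, level = as.character(lv),
        SCLC = fmt_n(sum(df[[f]][df$subtype == "SCLC"] == lv, na.rm = TRUE),
                     n_by[["SCLC"]]),
        NSCLC = fmt_n(sum(df[[f]][df$subtype == "NSCLC"] == lv, na.rm = TRUE),
                      n_by[["NSCLC"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
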