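as_binary_labels <- function(labels, positive_class = "NSCLC") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  labels == positive_class
}

# Mann–Whitney kernel placements. For scores of m positives and n negatives,
# psi(x, y) is 1 when x > y, 0.5 on ties, 0 otherwise; the AUC is its mean
# over all m*n pairs, and the per-observation means (placement values) carry
# the covariance structure used by the DeLong variance estimator.
delong_placements <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' AUC of a score vector with its DeLong variance
#'
#' Nonparametric (trapezoidal / Mann–Whitney) AUC and the DeLong
#' placement-value variance estimate. Works for continuous scores and for
#' 0/1 dichotomous predictions alike; in the dichotomous case the AUC
#' equals (sensitivity + specificity) / 2.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels class labels; character labels are compared against
#'   `positive_class`.
#' @param positive_class positive class for character labels.
#' @return list: `auc`, `var`, `m` (positives), `n` (negatives).
#' @export
auc_delong <- function(scores, labels, positive_class = "NSCLC") {
  pos <- as_binary_labels(labels, positive_class)
  if (!any(pos) || all(pos)) {
    stop_casefindr("AUC is undefined: one class is absent",
                   class = "casefindr_degenerate_error")
  }
  pl <- delong_placements(scores, pos)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  list(auc = pl$auc, var = v, m = pl$m, n = pl$n)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scoring rules evaluated on the same patients
#' (a paired design, so the AUC estimates are correlated). AUCs come from
#' the Mann–Whitney kernel; their variance–covariance from DeLong placement
#' values; the test statistic is `(auc_a - auc_b)^2 / var(diff)`, referred
#' to a chi-square with 1 degree of freedom (equivalently a two-sided
#' z-test).
#'
#' @param scores_a,scores_b paired score vectors on the same patients.
#' @param labels gold-standard labels.
#' @param positive_class positive class for character labels.
#' @return object of class `roc_comparison`: `auc_a`, `auc_b`,
#'   `auc_difference`, `var_difference`, `chi_square`, `df`, `p_value`,
#'   `degenerate` (TRUE when the AUCs differ but the variance of the
#'   difference is zero, in which case `p_value` is `NA`).
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           positive_class = "NSCLC") {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- as_binary_labels(labels, positive_class)
  if (!any(pos) || all(pos)) {
    stop_casefindr("AUC is undefined: one class is absent",
                   class = "casefindr_degenerate_error")
  }
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / pa$m + s01 / pa$n
  diff <- pa$auc - pb$auc
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  degenerate <- FALSE
  if (var_diff <= .Machine$double.eps^0.5) {
    if (abs(diff) <= .Machine$double.eps^0.5) {
      chi <- 0
      p <- 1
    } else {
      degenerate <- TRUE
      chi <- NA_real_
      p <- NA_real_
    }
  } else {
    chi <- diff^2 / var_diff
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, auc_difference = diff,
                 var_a = s[1, 1], var_b = s[2, 2], var_difference = var_diff,
                 chi_square = chi, df = 1L, p_value = p,
                 degenerate = degenerate),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat("<roc_comparison> DeLong test for correlated ROC curves\n")
  cat(sprintf("  AUC A = %.4f, AUC B = %.4f, difference = %.4f\n",
              x$auc_a, x$auc_b, x$auc_difference))
  if (x$degenerate) {
    cat("  degenerate: unequal AUCs with zero estimated variance of the difference\n")
  } else {
    cat(sprintf("  chi-square = %.3f (df = %d), p = %.4g\n",
                x$chi_square, x$df, x$p_value))
  }
  invisible(x)
}
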