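#' McFadden pseudo R-squared of a fitted logistic model
#'
#' `1 - logLik(model) / logLik(intercept-only model)`; 0 for a model no
#' better than the null, approaching (but never reaching) 1 for a model
#' that concentrates all likelihood on the observed outcomes.
#'
#' @param model a fitted binomial `glm`.
#' @param null_model the intercept-only fit on the same data.
#' @export
mcfadden_r2 <- function(model, null_model) {
  ll <- as.numeric(stats::logLik(model))
  ll0 <- as.numeric(stats::logLik(null_model))
  if (ll0 == 0) return(0)
  1 - ll / ll0
}

#' Hierarchical logistic robustness analysis
#'
#' Tests whether a case-finding algorithm's agreement with the gold
#' standard is robust to patient covariates, using the two-step hierarchy
#' standard in validation studies: step 1 regresses the gold-standard
#' subtype on the covariates alone; step 2 adds the algorithm's prediction;
#' the increment in McFadden pseudo R-squared is the variance uniquely
#' attributable to the algorithm. Covariate-by-algorithm interactions are
#' then screened one at a time against the step-2 model by likelihood-ratio
#' test.
#'
#' Complete cases only: rows with any missing covariate, label, or
#' prediction are dropped (and counted in `n_dropped`). Fits showing signs
#' of complete separation (fitted probabilities numerically 0/1) are
#' flagged rather than silently reported.
#'
#' @param labels gold-standard labels (vector, or data.frame with
#'   `patient_id`/`subtype`).
#' @param covariates data.frame of covariates (one row per patient, in
#'   label order when vectors are given, else carrying `patient_id`).
#' @param algorithm_predictions predicted classes (vector or data.frame
#'   with `patient_id`/`predicted`).
#' @param positive_class positive class for character labels/predictions.
#' @param interactions fit one-at-a-time covariate x algorithm
#'   interactions (default TRUE).
#' @return list of class `hierarchical_logistic`: `pseudo_r2_covariates`,
#'   `pseudo_r2_full`, `delta_pseudo_r2`, `p_algorithm` (LR test of the
#'   algorithm term), `coefficients` (step-2 summary table),
#'   `covariate_p` (step-1 per-covariate LR p-values), `interaction_p`,
#'   `n_used`, `n_dropped`, `separation_flag`.
#' @export
hierarchical_logistic <- function(labels, covariates, algorithm_predictions,
                                  positive_class = "NSCLC",
                                  interactions = TRUE) {
  if (is.data.frame(labels)) {
    ids <- labels$patient_id
    y <- as_binary_labels(labels$subtype, positive_class)
    if (is.data.frame(algorithm_predictions)) {
      algorithm_predictions <-
        algorithm_predictions$predicted[match(ids, algorithm_predictions$patient_id)]
    }
    if ("patient_id" %in% names(covariates)) {
      covariates <- covariates[match(ids, covariates$patient_id),
                               setdiff(names(covariates), "patient_id"),
                               drop = FALSE]
    }
  } else {
    y <- as_binary_labels(labels, positive_class)
  }
  alg <- as.numeric(as_binary_labels(algorithm_predictions, positive_class))
  stopifnot(length(y) == nrow(covariates), length(alg) == length(y))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(stats::na.omit(v))) < 2L) {
      stop_casefindr("covariate '%s' is constant", nm,
                     class = "casefindr_contract_error")
    }
  }

  dat <- data.frame(.y = as.numeric(y), covariates, .alg = alg,
                    check.names = FALSE)
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  cov_names <- names(covariates)

  f_null <- stats::as.formula(".y ~ 1")
  f_cov <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", cov_names),
                                                 collapse = " + ")))
  f_full <- stats::update(f_cov, . ~ . + .alg)
  m_null <- stats::glm(f_null, family = stats::binomial(), data = dat)
  m_cov <- stats::glm(f_cov, family = stats::binomial(), data = dat)
  m_full <- stats::glm(f_full, family = stats::binomial(), data = dat)

  eps <- 1e-8
  separation_flag <- any(stats::fitted(m_full) < eps) ||
    any(stats::fitted(m_full) > 1 - eps) || !m_full$converged

  lr_p <- function(small, big) {
    dev <- stats::deviance(small) - stats::deviance(big)
    dfd <- small$df.residual - big$df.residual
    stats::pchisq(max(dev, 0), df = max(dfd, 1L), lower.tail = FALSE)
  }

  covariate_p <- vapply(cov_names, function(nm) {
    others <- setdiff(cov_names, nm)
    f_red <- if (length(others) == 0L) f_null else
      stats::as.formula(paste(".y ~", paste(sprintf("`%s`", others),
                                            collapse = " + ")))
    lr_p(stats::glm(f_red, family = stats::binomial(), data = dat), m_cov)
  }, numeric(1))

  interaction_p <- NULL
  if (interactions) {
    interaction_p <- vapply(cov_names, function(nm) {
      f_int <- stats::update(f_full,
                             stats::as.formula(sprintf(". ~ . + `%s`:.alg", nm)))
      m_int <- suppressWarnings(stats::glm(f_int, family = stats::binomial(),
                                           data = dat))
      lr_p(m_full, m_int)
    }, numeric(1))
  }

  coefs <- as.data.frame(summary(m_full)$coefficients)
  names(coefs) <- c("estimate", "std_error", "z", "p_value")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL

  structure(list(
    pseudo_r2_covariates = mcfadden_r2(m_cov, m_null),
    pseudo_r2_full = mcfadden_r2(m_full, m_null),
    delta_pseudo_r2 = mcfadden_r2(m_full, m_null) - mcfadden_r2(m_cov, m_null),
    p_covariate_block = lr_p(m_null, m_cov),
    p_algorithm = lr_p(m_cov, m_full),
    coefficients = coefs[c("term", "estimate", "std_error", "z", "p_value")],
    covariate_p = covariate_p,
    interaction_p = interaction_p,
    n_used = nrow(dat), n_dropped = n_dropped,
    separation_flag = separation_flag),
    class = "hierarchical_logistic")
}

#' @export
print.hierarchical_logistic <- function(x, ...) {
  cat("<hierarchical_logistic> two-step covariate robustness analysis\n")
  cat(sprintf("  step 1 (covariates only): pseudo R2 = %.4f (p = %.3g)\n",
              x$pseudo_r2_covariates, x$p_covariate_block))
  cat(sprintf("  step 2 (+ algorithm):     pseudo R2 = %.4f\n", x$pseudo_r2_full))
  cat(sprintf("  delta pseudo R2 attributable to the algorithm = %.4f (p = %.3g)\n",
              x$delta_pseudo_r2, x$p_algorithm))
  if (x$separation_flag) cat("  WARNING: possible complete separation\n")
  invisible(x)
}
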