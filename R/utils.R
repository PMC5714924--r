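`%||%` <- function(x, y) if (is.null(x)) y else x

#' casefindr: claims-based NSCLC case finding and validation
#'
#' Classifies lung-cancer patients in administrative claims as NSCLC vs.
#' SCLC from the treatments and tests they received, and provides the
#' diagnostic-accuracy, ROC-comparison and covariate-robustness statistics
#' used to validate such claims-based phenotyping rules, plus a synthetic
#' claims generator for end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

CODE_SYSTEMS <- c("GPI", "HCPCS", "CPT", "ICD9_PROC", "ICD10_PROC",
                  "ICD9_DX", "ICD10_DX")
SUBTYPES <- c("NSCLC", "SCLC")
STAGES <- c("0", "IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV", "Limited")

stop_casefindr <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "casefindr_error")))
}

assert_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_casefindr("%s file is missing required column(s): %s",
                   what, paste(missing, collapse = ", "),
                   class = "casefindr_schema_error")
  }
  invisible(df)
}

# Parses ISO-8601 dates, reporting 1-based data-row numbers of failures.
parse_dates <- function(x, what, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  bad <- c(bad, which(is.na(x) | !nzchar(as.character(x))))
  bad <- sort(unique(bad))
  if (length(bad) > 0L) {
    stop_casefindr("%s: unparseable or missing date in column '%s' at row(s) %s",
                   what, column,
                   paste(utils::head(bad, 5L), collapse = ", "),
                   class = "casefindr_parse_error")
  }
  d
}
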