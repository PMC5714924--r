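#' Read a claims file
#'
#' Claims are one row per billed service line with columns `patient_id`,
#' `service_date` (ISO-8601), `code_system` (one of GPI, HCPCS, CPT,
#' ICD9_PROC, ICD10_PROC, ICD9_DX, ICD10_DX) and `code`. Exact duplicate
#' lines — same patient, date, system and code — carry no extra information
#' for criteria matching and are dropped.
#'
#' @param path path to a delimited text file (CSV).
#' @param quiet suppress the row-count message.
#' @return data.frame of deduplicated claim lines, `service_date` as `Date`.
#' @export
read_claims <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_claims(df, what = basename(path), quiet = quiet)
}

validate_claims <- function(df, what = "claims", quiet = FALSE) {
  assert_columns(df, c("patient_id", "service_date", "code_system", "code"), what)
  df$service_date <- parse_dates(df$service_date, what, "service_date")
  bad_sys <- setdiff(unique(df$code_system), CODE_SYSTEMS)
  if (length(bad_sys) > 0L) {
    stop_casefindr("%s: unknown code_system value(s): %s", what,
                   paste(bad_sys, collapse = ", "),
                   class = "casefindr_validation_error")
  }
  if (any(!nzchar(df$code))) {
    stop_casefindr("%s: empty code value(s)", what,
                   class = "casefindr_validation_error")
  }
  n_in <- nrow(df)
  df <- df[!duplicated(df[c("patient_id", "service_date", "code_system", "code")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  if (!quiet) {
    message(sprintf("%s: %d claim lines read, %d retained after deduplication",
                    what, n_in, nrow(df)))
  }
  df
}

#' Read an enrollment file
#'
#' Enrollment spans have columns `patient_id`, `start`, `end` (ISO-8601
#' dates, `start <= end`). Overlapping or abutting spans for the same
#' patient are merged so that stored spans are disjoint.
#'
#' @inheritParams read_claims
#' @return data.frame of merged spans per patient.
#' @export
read_enrollment <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_enrollment(df, what = basename(path), quiet = quiet)
}

validate_enrollment <- function(df, what = "enrollment", quiet = FALSE) {
  assert_columns(df, c("patient_id", "start", "end"), what)
  df$start <- parse_dates(df$start, what, "start")
  df$end <- parse_dates(df$end, what, "end")
  if (any(df$start > df$end)) {
    stop_casefindr("%s: span(s) with start after end", what,
                   class = "casefindr_validation_error")
  }
  n_in <- nrow(df)
  df <- merge_spans(df)
  if (!quiet) {
    message(sprintf("%s: %d spans read, %d after merging", what, n_in, nrow(df)))
  }
  df
}

#' Merge overlapping or abutting enrollment spans
#'
#' Two spans for the same patient are merged when they overlap or abut
#' (one ends the day before the next begins): continuous coverage is what
#' matters for enrollment checks, not how the payer happened to slice it.
#'
#' @param spans data.frame with `patient_id`, `start`, `end` (`Date`).
#' @return data.frame of disjoint spans, sorted by patient and start date.
#' @export
merge_spans <- function(spans) {
  if (nrow(spans) == 0L) return(spans)
  spans <- spans[order(spans$patient_id, spans$start, spans$end), , drop = FALSE]
  pieces <- lapply(split(spans, spans$patient_id), function(s) {
    start <- as.integer(s$start)
    end <- as.integer(s$end)
    keep_start <- start[1]
    keep_end <- end[1]
    out_start <- integer(0)
    out_end <- integer(0)
    for (i in seq_len(nrow(s))[-1]) {
      if (start[i] <= keep_end + 1L) {
        keep_end <- max(keep_end, end[i])
      } else {
        out_start <- c(out_start, keep_start); out_end <- c(out_end, keep_end)
        keep_start <- start[i]; keep_end <- end[i]
      }
    }
    out_start <- c(out_start, keep_start); out_end <- c(out_end, keep_end)
    data.frame(patient_id = s$patient_id[1],
               start = as.Date(out_start, origin = "1970-01-01"),
               end = as.Date(out_end, origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read a patient file
#'
#' Columns: `patient_id`, `index_date`, `age_at_index`, `gender`, `bmi`,
#' `dci_score`, `cancer_stage`, `insurance`, `region`. The index date is the
#' anchor for all observation windows (in the motivating design, the
#' earliest lung-cancer precertification date).
#'
#' @inheritParams read_claims
#' @export
read_patients <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_patients(df, what = basename(path), quiet = quiet)
}

validate_patients <- function(df, what = "patients", quiet = FALSE) {
  assert_columns(df, c("patient_id", "index_date", "age_at_index"), what)
  df$patient_id <- as.character(df$patient_id)
  df$index_date <- parse_dates(df$index_date, what, "index_date")
  if (any(df$age_at_index < 0, na.rm = TRUE)) {
    stop_casefindr("%s: negative age_at_index", what,
                   class = "casefindr_validation_error")
  }
  if ("cancer_stage" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$cancer_stage)), STAGES)
    if (length(bad) > 0L) {
      stop_casefindr("%s: cancer_stage value(s) outside recognised levels: %s",
                     what, paste(bad, collapse = ", "),
                     class = "casefindr_validation_error")
    }
  }
  if (anyDuplicated(df$patient_id)) {
    stop_casefindr("%s: duplicated patient_id", what,
                   class = "casefindr_validation_error")
  }
  if (!quiet) message(sprintf("%s: %d patients read", what, nrow(df)))
  df
}

#' Read a validation-label file
#'
#' Gold-standard subtype per patient: columns `patient_id`, `subtype`
#' (NSCLC or SCLC). Exactly one label per patient; any other subtype value
#' is rejected (patients with missing or ambiguous histology are excluded
#' before labels are produced).
#'
#' @inheritParams read_claims
#' @export
read_labels <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_labels(df, what = basename(path), quiet = quiet)
}

validate_labels <- function(df, what = "labels", quiet = FALSE) {
  assert_columns(df, c("patient_id", "subtype"), what)
  bad <- setdiff(unique(df$subtype), SUBTYPES)
  if (length(bad) > 0L) {
    stop_casefindr("%s: subtype must be NSCLC or SCLC; found: %s", what,
                   paste(bad, collapse = ", "),
                   class = "casefindr_validation_error")
  }
  if (anyDuplicated(df$patient_id)) {
    stop_casefindr("%s: more than one label for some patient(s)", what,
                   class = "casefindr_validation_error")
  }
  if (!quiet) message(sprintf("%s: %d labels read", what, nrow(df)))
  df
}

#' Load a full cohort from delimited files
#'
#' Convenience wrapper that reads and validates the four cohort tables.
#'
#' @param claims_path,enrollment_path,patients_path,labels_path CSV paths.
#' @param quiet suppress row-count messages.
#' @return list with elements `claims`, `spans`, `patients`, `labels`.
#' @export
load_cohort <- function(claims_path, enrollment_path, patients_path,
                        labels_path, quiet = FALSE) {
  list(claims = read_claims(claims_path, quiet = quiet),
       spans = read_enrollment(enrollment_path, quiet = quiet),
       patients = read_patients(patients_path, quiet = quiet),
       labels = read_labels(labels_path, quiet = quiet))
}

#' Check continuous enrollment around an index date
#'
#' The window is `[index_date - pre_months * days_per_month,
#' index_date + post_months * days_per_month]`, inclusive at both ends;
#' months are counted as 30-day blocks to avoid calendar ambiguity. The
#' patient passes when no uncovered run of days inside the window exceeds
#' `gap_tolerance_days` (0 = strictly continuous coverage).
#'
#' @param spans data.frame of enrollment spans for one patient
#'   (`start`, `end` as `Date`); need not be pre-merged.
#' @param index_date the anchor date.
#' @param pre_months,post_months window extent, in 30-day months.
#' @param gap_tolerance_days longest permissible uncovered run.
#' @param days_per_month days per "month" of window (default 30).
#' @return `TRUE` or `FALSE`; an empty span set is simply `FALSE`.
#' @export
check_continuous_enrollment <- function(spans, index_date,
                                        pre_months = 3, post_months = 3,
                                        gap_tolerance_days = 0,
                                        days_per_month = 30) {
  stopifnot(pre_months >= 0, post_months >= 0, gap_tolerance_days >= 0)
  index_date <- as.Date(index_date)
  w0 <- as.integer(index_date) - as.integer(pre_months * days_per_month)
  w1 <- as.integer(index_date) + as.integer(post_months * days_per_month)
  if (nrow(spans) == 0L) return((w1 - w0 + 1L) <= gap_tolerance_days)
  s <- as.integer(pmax(as.Date(spans$start), as.Date(w0, origin = "1970-01-01")))
  e <- as.integer(pmin(as.Date(spans$end), as.Date(w1, origin = "1970-01-01")))
  keep <- s <= e
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0L) return((w1 - w0 + 1L) <= gap_tolerance_days)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  # longest uncovered run: before first span, between spans, after last
  max_gap <- s[1] - w0
  cover_end <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cover_end + 1L) max_gap <- max(max_gap, s[i] - cover_end - 1L)
    cover_end <- max(cover_end, e[i])
  }
  max_gap <- max(max_gap, w1 - cover_end)
  max_gap <= gap_tolerance_days
}

#' Select the eligible cohort
#'
#' Applies the cohort-entry rules in a fixed, documented order and tallies
#' attrition per exclusion reason: (1) missing validation label (when
#' `labels` is supplied), (2) index date outside the intake window,
#' (3) age below `min_age`, (4) continuous-enrollment failure. A patient is
#' tallied under the first rule that removes them, so
#' `retained + sum(excluded)` always equals the input count.
#'
#' @param patients patient data.frame (`patient_id`, `index_date`,
#'   `age_at_index`).
#' @param spans enrollment data.frame for the whole cohort.
#' @param labels optional label data.frame; `NULL` skips the label rule.
#' @param intake_start,intake_end intake period (index date must fall
#'   inside, inclusive).
#' @param min_age minimum age at index, in years (default 18: adults).
#' @inheritParams check_continuous_enrollment
#' @return list with `eligible` (patient data.frame subset) and `attrition`
#'   (data.frame of reason / n, including the retained count).
#' @export
select_eligible <- function(patients, spans, labels = NULL,
                            intake_start, intake_end, min_age = 18,
                            pre_months = 3, post_months = 3,
                            gap_tolerance_days = 0, days_per_month = 30) {
  intake_start <- as.Date(intake_start); intake_end <- as.Date(intake_end)
  stopifnot(intake_start <= intake_end)
  n0 <- nrow(patients)
  reason <- rep(NA_character_, n0)

  if (!is.null(labels)) {
    reason[!(patients$patient_id %in% labels$patient_id)] <- "missing_label"
  }
  in_intake <- patients$index_date >= intake_start &
    patients$index_date <= intake_end
  reason[is.na(reason) & !in_intake] <- "outside_intake_window"
  reason[is.na(reason) & patients$age_at_index < min_age] <- "below_min_age"

  spans_by_pt <- split(spans, spans$patient_id)
  empty_spans <- spans[0, , drop = FALSE]
  todo <- which(is.na(reason))
  for (i in todo) {
    ok <- check_continuous_enrollment(
      spans_by_pt[[patients$patient_id[i]]] %||% empty_spans,
      patients$index_date[i], pre_months, post_months,
      gap_tolerance_days, days_per_month)
    if (!ok) reason[i] <- "enrollment_gap"
  }

  reasons <- c("missing_label", "outside_intake_window", "below_min_age",
               "enrollment_gap")
  attrition <- data.frame(
    reason = c(reasons, "retained"),
    n = c(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                 integer(1)),
          sum(is.na(reason))),
    stringsAsFactors = FALSE)
  eligible <- patients[is.na(reason), , drop = FALSE]
  rownames(eligible) <- NULL
  list(eligible = eligible, attrition = attrition)
}
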