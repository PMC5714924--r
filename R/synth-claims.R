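#' Configuration for the synthetic claims generator
#'
#' Defaults emulate the validation cohort the package's statistics are
#' designed for: 1,353 lung-cancer patients at 80 percent NSCLC
#' prevalence, subtype demographics matching a commercially insured US
#' cohort (age ~60, half male, BMI ~26, high comorbidity burden, mostly
#' stage IIIA–IV), an intake window of 2014-06-01 to 2015-10-31, and
#' treatment-assignment probabilities whose closed-form operating point
#' (see [expected_performance()]) is sensitivity 0.950 and specificity
#' 0.810 under the exclusion-first case-finding policy.
#'
#' Treatment assignment: each patient receives, with probability
#' `p_concordant_*`, a first-line regimen drawn uniformly from their true
#' subtype's criterion list (for NSCLC, the drug regimens; PET imaging and
#' resection surgery are emitted independently with `p_pet_scan` /
#' `p_surgery`), and, with probability `p_crossover_*`, additionally a
#' regimen from the other subtype's list — the mechanism by which real
#' NSCLC/SCLC cohorts end up misclassified by treatment-based rules.
#' Crossover is parameterised per subtype because the two error directions
#' (an SCLC regimen vetoing a true NSCLC patient vs. an NSCLC regimen
#' rescuing an otherwise-unmatched true SCLC patient) have very different
#' rates at any realistic operating point.
#'
#' @param n_patients cohort size.
#' @param prevalence_nsclc probability a patient is truly NSCLC.
#' @param p_concordant_nsclc,p_concordant_sclc probability of receiving a
#'   regimen from the own-subtype list.
#' @param p_crossover_nsclc,p_crossover_sclc probability of additionally
#'   receiving a regimen from the other subtype's list.
#' @param p_pet_scan,p_surgery probabilities of PET imaging / lung
#'   resection claims (NSCLC arm only).
#' @param enrollment_violation_rate fraction of patients given an
#'   enrollment span that stops short of the post-index window.
#' @param intake_start,intake_end intake period for index dates.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @param demographics optional list overriding per-subtype demographic
#'   parameters (see `default_demographics()` in the source).
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 1353,
                                    prevalence_nsclc = 0.80,
                                    p_concordant_nsclc = 0.90,
                                    p_concordant_sclc = 0.62,
                                    p_crossover_nsclc = 0.043,
                                    p_crossover_sclc = 0.50,
                                    p_pet_scan = 0.90,
                                    p_surgery = 0.30,
                                    enrollment_violation_rate = 0,
                                    intake_start = "2014-06-01",
                                    intake_end = "2015-10-31",
                                    seed = 1,
                                    demographics = NULL) {
  probs <- c(prevalence_nsclc, p_concordant_nsclc, p_concordant_sclc,
             p_crossover_nsclc, p_crossover_sclc, p_pet_scan, p_surgery,
             enrollment_violation_rate)
  stopifnot(n_patients > 0, all(probs >= 0 & probs <= 1))
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_nsclc = prevalence_nsclc,
                 p_concordant_nsclc = p_concordant_nsclc,
                 p_concordant_sclc = p_concordant_sclc,
                 p_crossover_nsclc = p_crossover_nsclc,
                 p_crossover_sclc = p_crossover_sclc,
                 p_pet_scan = p_pet_scan, p_surgery = p_surgery,
                 enrollment_violation_rate = enrollment_violation_rate,
                 intake_start = as.Date(intake_start),
                 intake_end = as.Date(intake_end),
                 seed = as.integer(seed),
                 demographics = demographics %||% default_demographics()),
            class = "synthetic_cohort_config")
}

# Per-subtype demographic parameters of the emulated cohort: age and BMI
# means/SDs, comorbidity index, gender split, Medicare-supplemental share,
# region and stage distributions.
default_demographics <- function() {
  list(
    SCLC = list(age_mean = 60.5, age_sd = 7.1, p_male = 0.507,
                bmi_mean = 26.9, bmi_sd = 6.7, dci_mean = 7.6, dci_sd = 2.9,
                p_medicare = 0.03,
                region_p = c(Northeast = 38, Midwest = 90, South = 84,
                             West = 58) / 270,
                stage_p = c("0" = 2, IA = 5, IB = 1, IIA = 3, IIB = 0,
                            IIIA = 10, IIIB = 13, IV = 205, Limited = 31) / 270),
    NSCLC = list(age_mean = 59.6, age_sd = 8.7, p_male = 0.498,
                 bmi_mean = 26.0, bmi_sd = 6.0, dci_mean = 7.4, dci_sd = 2.8,
                 p_medicare = 0.03,
                 region_p = c(Northeast = 186, Midwest = 330, South = 295,
                              West = 272) / 1083,
                 stage_p = c("0" = 0, IA = 3, IB = 12, IIA = 53, IIB = 36,
                             IIIA = 136, IIIB = 84, IV = 755, Limited = 4) / 1083))
}

# Criterion lists the generator samples regimens from: SCLC regimens are
# the case-finding algorithm's exclusion criteria; NSCLC drug regimens are
# its inclusion criteria minus the two procedure concepts (emitted
# separately).
generator_regimens <- function(algorithm) {
  roles <- vapply(algorithm$criteria, `[[`, character(1), "role")
  sclc <- algorithm$criteria[roles == "SCLC_exclusion"]
  incl <- algorithm$criteria[roles == "NSCLC_inclusion"]
  is_proc <- vapply(incl, function(cr)
    all(cr$components %in% c("pet_scan", "lung_resection")), logical(1))
  list(sclc = sclc, nsclc = incl[!is_proc],
       procedures = incl[is_proc])
}

# Emit dated claim lines realising one criterion: anchor 0-45 days after
# index (first-line treatment), combination components 0-10 days after the
# anchor so every component sits inside one 21-day cycle and the whole
# regimen inside the index +/- 90 day evaluation window. Returns parallel
# vectors (dates as integer days) for fast assembly.
emit_regimen_claims <- function(index_int, criterion, codelists) {
  anchor <- index_int + sample.int(46L, 1L) - 1L
  k <- length(criterion$components)
  offsets <- c(0L, if (k > 1L) sample.int(11L, k - 1L, replace = TRUE) - 1L)
  sys <- character(k); code <- character(k)
  for (j in seq_len(k)) {
    cl <- codelists[[criterion$components[j]]]
    pick <- sample.int(nrow(cl), 1L)
    sys[j] <- cl$system[pick]; code[j] <- cl$code[pick]
  }
  list(date = anchor + offsets, system = sys, code = code)
}

emit_concept_claim <- function(index_int, concept, codelists, offset_range) {
  cl <- codelists[[concept]]
  pick <- sample.int(nrow(cl), 1L)
  list(date = index_int + sample(offset_range, 1L),
       system = cl$system[pick], code = cl$code[pick])
}

#' Generate a synthetic lung-cancer claims cohort
#'
#' Produces the four cohort tables (patients, labels, claims, enrollment
#' spans) plus a per-patient truth log recording exactly which regimens
#' and procedures were assigned, so expected criterion matches — and hence
#' the expected classification — can be recomputed independently of the
#' matching engine. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_cohort_config()].
#' @param codelists code registry used to emit claims.
#' @param algorithm the case-finding algorithm whose criterion lists
#'   define the subtype-specific regimen pools (default: the bundled one).
#' @return list of class `synthetic_cohort`: `patients`, `labels`,
#'   `claims`, `spans`, `truth`, `config`.
#' @export
generate_cohort <- function(config, codelists, algorithm = NULL) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  algorithm <- algorithm %||% build_case_finding_algorithm(codelists = codelists)
  pools <- generator_regimens(algorithm)
  if (length(pools$sclc) == 0L || length(pools$nsclc) == 0L) {
    stop_casefindr("algorithm provides no regimen pool for one subtype",
                   class = "casefindr_config_error")
  }
  for (cr in c(pools$sclc, pools$nsclc, pools$procedures))
    for (cp in cr$components) resolve_concept(cp, codelists)

  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  subtype <- ifelse(stats::runif(n) < config$prevalence_nsclc, "NSCLC", "SCLC")
  intake_days <- as.integer(config$intake_end) - as.integer(config$intake_start)
  index_int <- as.integer(config$intake_start) +
    sample.int(intake_days + 1L, n, replace = TRUE) - 1L

  demo <- config$demographics
  draw_demo <- function(st, k) {
    d <- demo[[st]]
    data.frame(
      age_at_index = pmax(18, round(stats::rnorm(k, d$age_mean, d$age_sd))),
      gender = ifelse(stats::runif(k) < d$p_male, "male", "female"),
      bmi = round(pmax(13, stats::rnorm(k, d$bmi_mean, d$bmi_sd)), 1),
      dci_score = pmax(0, round(stats::rnorm(k, d$dci_mean, d$dci_sd))),
      insurance = ifelse(stats::runif(k) < d$p_medicare,
                         "medicare_supplemental", "commercial"),
      region = sample(names(d$region_p), k, replace = TRUE, prob = d$region_p),
      cancer_stage = sample(names(d$stage_p), k, replace = TRUE,
                            prob = d$stage_p),
      stringsAsFactors = FALSE)
  }
  demo_df <- draw_demo("NSCLC", n)  # allocate; overwritten per subtype below
  for (st in c("SCLC", "NSCLC")) {
    w <- which(subtype == st)
    if (length(w) > 0L) demo_df[w, ] <- draw_demo(st, length(w))
  }
  patients <- cbind(
    data.frame(patient_id = ids,
               index_date = as.Date(index_int, origin = "1970-01-01"),
               stringsAsFactors = FALSE),
    demo_df)
  rownames(patients) <- NULL

  is_nsclc <- subtype == "NSCLC"
  concordant <- stats::runif(n) <
    ifelse(is_nsclc, config$p_concordant_nsclc, config$p_concordant_sclc)
  crossover <- stats::runif(n) <
    ifelse(is_nsclc, config$p_crossover_nsclc, config$p_crossover_sclc)
  pet <- is_nsclc & stats::runif(n) < config$p_pet_scan
  surgery <- is_nsclc & stats::runif(n) < config$p_surgery
  violation <- stats::runif(n) < config$enrollment_violation_rate

  acc <- vector("list", 4L * n)
  acc_pid <- vector("list", 4L * n)
  n_acc <- 0L
  add <- function(pid, piece) {
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- piece
    acc_pid[[n_acc]] <<- rep(pid, length(piece$date))
  }
  regimen <- rep(NA_character_, n)
  crossover_regimen <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    own_pool <- if (is_nsclc[i]) pools$nsclc else pools$sclc
    other_pool <- if (is_nsclc[i]) pools$sclc else pools$nsclc
    if (concordant[i]) {
      j <- sample.int(length(own_pool), 1L)
      regimen[i] <- own_pool[[j]]$name
      add(ids[i], emit_regimen_claims(index_int[i], own_pool[[j]], codelists))
    }
    if (crossover[i]) {
      j <- sample.int(length(other_pool), 1L)
      crossover_regimen[i] <- other_pool[[j]]$name
      add(ids[i], emit_regimen_claims(index_int[i], other_pool[[j]], codelists))
    }
    if (pet[i])
      add(ids[i], emit_concept_claim(index_int[i], "pet_scan", codelists, -30:10))
    if (surgery[i])
      add(ids[i], emit_concept_claim(index_int[i], "lung_resection", codelists, 0:60))
  }
  acc <- acc[seq_len(n_acc)]
  claims <- data.frame(
    patient_id = unlist(acc_pid[seq_len(n_acc)], use.names = FALSE) %||% character(0),
    service_date = as.Date(unlist(lapply(acc, `[[`, "date"), use.names = FALSE) %||%
                             integer(0), origin = "1970-01-01"),
    code_system = unlist(lapply(acc, `[[`, "system"), use.names = FALSE) %||% character(0),
    code = unlist(lapply(acc, `[[`, "code"), use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  claims <- claims[!duplicated(claims), , drop = FALSE]
  rownames(claims) <- NULL

  # enrollment: generous coverage around the index except for violators,
  # whose span stops 45 days post-index (inside the 90-day post window)
  pre_len <- 120L + sample.int(240L, n, replace = TRUE)
  post_len <- 120L + sample.int(240L, n, replace = TRUE)
  span_end <- ifelse(violation, index_int + 45L, index_int + post_len)
  spans <- data.frame(patient_id = ids,
                      start = as.Date(index_int - pre_len, origin = "1970-01-01"),
                      end = as.Date(span_end, origin = "1970-01-01"),
                      stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = ids, subtype = subtype,
                      concordant = concordant, regimen = regimen,
                      crossover = crossover,
                      crossover_regimen = crossover_regimen,
                      pet_scan = pet, surgery = surgery,
                      enrollment_violation = violation,
                      stringsAsFactors = FALSE)

  structure(list(patients = patients,
                 labels = data.frame(patient_id = ids, subtype = subtype,
                                     stringsAsFactors = FALSE),
                 claims = claims, spans = spans, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%.1f%% NSCLC), %d claim lines, seed %d\n",
              nrow(x$patients),
              100 * mean(x$labels$subtype == "NSCLC"),
              nrow(x$claims), x$config$seed))
  invisible(x)
}

#' Closed-form operating point implied by a generator configuration
#'
#' Under the exclusion-first policy with SCLC as the default label, and
#' with the generator's sampling scheme (own-subtype regimen with
#' probability `p_concordant`, other-subtype regimen with `p_crossover`,
#' PET/surgery in the NSCLC arm only, no code noise), the expected
#' operating point has a closed form:
#'
#' * a true NSCLC patient is predicted NSCLC iff no SCLC regimen crossed
#'   over AND at least one NSCLC criterion was emitted, so
#'   `Se = (1 - p_crossover_nsclc) * (1 - (1 - p_concordant_nsclc) *
#'   (1 - p_pet_scan) * (1 - p_surgery))`;
#' * a true SCLC patient is predicted NSCLC iff no own SCLC regimen was
#'   emitted (which would veto) AND an NSCLC regimen crossed over, so
#'   `Sp = 1 - (1 - p_concordant_sclc) * p_crossover_sclc`.
#'
#' The NSCLC regimen pool shares no drug with the SCLC exclusion list, so
#' concordant NSCLC claims can never spuriously fire an exclusion and the
#' formulas are exact, not approximations.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list: `sensitivity`, `specificity`.
#' @export
expected_performance <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  coverage <- 1 - (1 - config$p_concordant_nsclc) *
    (1 - config$p_pet_scan) * (1 - config$p_surgery)
  list(sensitivity = (1 - config$p_crossover_nsclc) * coverage,
       specificity = 1 - (1 - config$p_concordant_sclc) * config$p_crossover_sclc)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("claims.csv", "enrollment.csv", "patients.csv",
                            "labels.csv", "truth.csv"))
  utils::write.csv(cohort$claims, paths[1], row.names = FALSE)
  utils::write.csv(cohort$spans, paths[2], row.names = FALSE)
  utils::write.csv(cohort$patients, paths[3], row.names = FALSE)
  utils::write.csv(cohort$labels, paths[4], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[5], row.names = FALSE)
  invisible(paths)
}
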