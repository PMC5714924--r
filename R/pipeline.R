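#' Worked-example validation of a bare 2x2 table
#'
#' Computes the full diagnostic-accuracy report directly from published
#' cross-tabulation counts, for re-analysing printed validation tables
#' without patient-level data.
#'
#' @param tp,fp,fn,tn counts (predicted-positive/label-positive first).
#' @param ... passed to [accuracy_measures()].
#' @export
validate_table <- function(tp, fp, fn, tn, ...) {
  accuracy_measures(confusion_counts(tp = tp, fp = fp, fn = fn, tn = tn), ...)
}

resolve_algorithm <- function(algorithm, codelists) {
  if (inherits(algorithm, "case_finding_algorithm")) return(algorithm)
  switch(algorithm,
         case_finding = build_case_finding_algorithm(codelists = codelists),
         control = build_control_algorithm(codelists = codelists),
         {
           if (!file.exists(algorithm)) {
             stop_casefindr("unknown algorithm '%s' (use 'case_finding', 'control', or a YAML path)",
                            algorithm, class = "casefindr_usage_error")
           }
           read_algorithm(algorithm, codelists = codelists)
         })
}

#' Run the full case-finding pipeline
#'
#' Simulate (optionally) or load a cohort, apply eligibility rules,
#' classify with the chosen algorithm, validate against the gold-standard
#' labels, and write all artifacts (predictions, attrition tally, accuracy
#' report, run metadata) to an output directory.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `simulate` (optional list of [synthetic_cohort_config()] arguments;
#'   when absent, `claims`/`enrollment`/`patients`/`labels` file paths are
#'   required), `algorithm` ("case_finding", "control", or a YAML path),
#'   `codelists` (registry path; default the bundled synthetic registry),
#'   `intake_start`/`intake_end`, `min_age`, `pre_months`/`post_months`,
#'   `gap_tolerance_days`, `out_dir`, `seed`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `predictions`, `attrition`, `accuracy`,
#'   `comparison` (DeLong case-finding vs. control, when both algorithms
#'   can be run), and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  codelists_path <- config$codelists %||% casefindr_example("concepts_synthetic.yaml")
  codelists <- read_codelists(codelists_path)
  algorithm <- resolve_algorithm(config$algorithm %||% "case_finding", codelists)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed) && is.null(sim_args$seed))
      sim_args$seed <- config$seed
    cohort <- generate_cohort(do.call(synthetic_cohort_config, sim_args),
                              codelists)
    claims <- cohort$claims; spans <- cohort$spans
    patients <- cohort$patients; labels <- cohort$labels
  } else {
    needed <- c("claims", "enrollment", "patients", "labels")
    missing <- needed[!vapply(needed, function(f) !is.null(config[[f]]),
                              logical(1))]
    if (length(missing) > 0L) {
      stop_casefindr("config must provide 'simulate' or input path(s): %s",
                     paste(missing, collapse = ", "),
                     class = "casefindr_usage_error")
    }
    loaded <- load_cohort(config$claims, config$enrollment, config$patients,
                          config$labels, quiet = quiet)
    claims <- loaded$claims; spans <- loaded$spans
    patients <- loaded$patients; labels <- loaded$labels
  }

  sel <- select_eligible(
    patients, spans, labels,
    intake_start = config$intake_start %||% "2014-06-01",
    intake_end = config$intake_end %||% "2015-10-31",
    min_age = config$min_age %||% 18,
    pre_months = config$pre_months %||% 3,
    post_months = config$post_months %||% 3,
    gap_tolerance_days = config$gap_tolerance_days %||% 0)
  eligible <- sel$eligible
  if (!quiet) {
    message(sprintf("eligibility: %d of %d patients retained",
                    nrow(eligible), nrow(patients)))
  }
  labels_el <- labels[labels$patient_id %in% eligible$patient_id, , drop = FALSE]

  predictions <- classify_cohort(eligible, claims, algorithm, codelists,
                                 quiet = quiet)
  ct <- confusion_table(predictions, labels_el)
  accuracy <- accuracy_measures(ct)

  out <- list(predictions = predictions, attrition = sel$attrition,
              confusion = ct, accuracy = accuracy)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p_pred <- file.path(config$out_dir, "predictions.csv")
    p_attr <- file.path(config$out_dir, "attrition.csv")
    p_rep <- file.path(config$out_dir, "accuracy.json")
    p_meta <- file.path(config$out_dir, "metadata.json")
    utils::write.csv(predictions, p_pred, row.names = FALSE)
    utils::write.csv(sel$attrition, p_attr, row.names = FALSE)
    jsonlite::write_json(accuracy_report(accuracy), p_rep, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    meta <- list(package = "casefindr",
                 version = as.character(utils::packageVersion("casefindr")),
                 algorithm = algorithm$name,
                 seed = config$seed %||% NA,
                 n_input = nrow(patients), n_eligible = nrow(eligible),
                 config_hash = sum(utils::head(
                   as.integer(charToRaw(paste(deparse(config), collapse = ""))),
                   1e6)),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- c(predictions = p_pred, attrition = p_attr,
                   report = p_rep, metadata = p_meta)
  }
  invisible(out)
}

#' Flatten a diagnostic_accuracy object for serialisation
#' @param da a `diagnostic_accuracy` object.
#' @return named list of estimate / CI triplets.
#' @export
accuracy_report <- function(da) {
  m <- da$measures
  rep <- lapply(seq_len(nrow(m)), function(i) {
    list(estimate = m$estimate[i], ci_low = m$ci_low[i], ci_high = m$ci_high[i])
  })
  names(rep) <- m$measure
  c(rep, list(n = da$table$total,
              table = list(tp = da$table$tp, fp = da$table$fp,
                           fn = da$table$fn, tn = da$table$tn)))
}
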