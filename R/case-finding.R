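#' Read an algorithm definition
#'
#' An algorithm definition is a YAML file with a `name`, a `policy`
#' (`exclusion_first` or `inclusion_only`), a binary `default_label`
#' (`NSCLC`, `SCLC`, or `UNCLASSIFIED` for research use), an `eval_window`
#' of `[days_before, days_after]` the index date, and a list of criteria
#' (name, role, components, combo_window_days).
#'
#' @param path YAML path.
#' @param codelists optional registry; when supplied, every component
#'   concept is checked to resolve, so configuration errors surface at
#'   build time rather than mid-classification.
#' @return object of class `case_finding_algorithm`.
#' @export
read_algorithm <- function(path, codelists = NULL) {
  raw <- yaml::read_yaml(path)
  build_algorithm(raw, codelists = codelists)
}

build_algorithm <- function(raw, codelists = NULL) {
  policy <- match.arg(raw$policy, c("exclusion_first", "inclusion_only"))
  default_label <- match.arg(raw$default_label, c("SCLC", "NSCLC", "UNCLASSIFIED"))
  criteria <- lapply(raw$criteria, function(cr) {
    cr$role <- match.arg(cr$role, c("SCLC_exclusion", "NSCLC_inclusion"))
    if (length(cr$components) == 0L) {
      stop_casefindr("criterion '%s' has no components", cr$name,
                     class = "casefindr_config_error")
    }
    cr$components <- as.character(cr$components)
    if (length(cr$components) >= 2L) {
      cr$combo_window_days <- as.integer(cr$combo_window_days %||% 21L)
    }
    cr
  })
  roles <- vapply(criteria, `[[`, character(1), "role")
  if (policy == "exclusion_first" && !any(roles == "SCLC_exclusion")) {
    stop_casefindr("exclusion_first policy requires at least one SCLC_exclusion criterion",
                   class = "casefindr_config_error")
  }
  if (!is.null(codelists)) {
    for (cr in criteria) for (cp in cr$components) resolve_concept(cp, codelists)
  }
  ew <- as.integer(raw$eval_window %||% c(90L, 90L))
  stopifnot(length(ew) == 2L, all(ew >= 0L))
  structure(list(name = raw$name %||% "algorithm", policy = policy,
                 default_label = default_label, eval_window = ew,
                 criteria = criteria),
            class = "case_finding_algorithm")
}

#' The NSCLC case-finding algorithm
#'
#' Builds the bundled treatments-and-tests rule set: nine SCLC-indicative
#' chemotherapy regimens as exclusion criteria and the NSCLC-indicative
#' tests and first-line regimens as inclusion criteria, classified under an
#' exclusion-first policy (an SCLC regimen vetoes an NSCLC label regardless
#' of what else the patient received).
#'
#' @param config optional path to an alternative YAML definition.
#' @param codelists optional registry for concept resolution checks.
#' @export
build_case_finding_algorithm <- function(config = NULL, codelists = NULL) {
  read_algorithm(config %||% casefindr_example("table1_case_finding.yaml"),
                 codelists = codelists)
}

#' The control algorithm
#'
#' The combined guideline list of lung-cancer first-line treatments and
#' tests — SCLC regimens included — used purely as NSCLC inclusion criteria
#' with no exclusions. A deliberately non-discriminating baseline.
#'
#' @inheritParams build_case_finding_algorithm
#' @export
build_control_algorithm <- function(config = NULL, codelists = NULL) {
  read_algorithm(config %||% casefindr_example("table1_control.yaml"),
                 codelists = codelists)
}

#' @export
print.case_finding_algorithm <- function(x, ...) {
  roles <- vapply(x$criteria, `[[`, character(1), "role")
  cat(sprintf("<case_finding_algorithm> %s\n", x$name))
  cat(sprintf("  policy: %s, default label: %s, window: index -%d/+%d days\n",
              x$policy, x$default_label, x$eval_window[1], x$eval_window[2]))
  cat(sprintf("  criteria: %d (%d SCLC exclusion, %d NSCLC inclusion)\n",
              length(x$criteria), sum(roles == "SCLC_exclusion"),
              sum(roles == "NSCLC_inclusion")))
  invisible(x)
}

#' Classify one patient from criterion matches
#'
#' Policy semantics: under `exclusion_first`, any matched SCLC-exclusion
#' criterion labels the patient SCLC; otherwise any matched NSCLC-inclusion
#' criterion labels them NSCLC; otherwise the default label applies. Under
#' `inclusion_only`, any matched inclusion criterion labels the patient
#' NSCLC, else the default. Only match booleans matter — never how many
#' claims supported a match. `decisive_rule` names the branch that fired,
#' for audit.
#'
#' @param matches list of `criterion_match`, one per algorithm criterion.
#' @param algorithm a `case_finding_algorithm`.
#' @return list: `predicted`, `matched_criteria` (character vector),
#'   `decisive_rule`.
#' @export
classify_patient <- function(matches, algorithm) {
  crit_names <- vapply(algorithm$criteria, `[[`, character(1), "name")
  match_names <- vapply(matches, `[[`, character(1), "name")
  if (!identical(sort(match_names), sort(crit_names))) {
    stop_casefindr("matches do not cover the algorithm's criteria",
                   class = "casefindr_contract_error")
  }
  ord <- match(crit_names, match_names)
  matched <- vapply(matches, `[[`, logical(1), "matched")[ord]
  roles <- vapply(algorithm$criteria, `[[`, character(1), "role")
  matched_criteria <- crit_names[matched]

  if (algorithm$policy == "exclusion_first") {
    excl <- matched & roles == "SCLC_exclusion"
    incl <- matched & roles == "NSCLC_inclusion"
    if (any(excl)) {
      predicted <- "SCLC"
      rule <- paste0("sclc_exclusion:", crit_names[which(excl)[1]])
    } else if (any(incl)) {
      predicted <- "NSCLC"
      rule <- paste0("nsclc_inclusion:", crit_names[which(incl)[1]])
    } else {
      predicted <- algorithm$default_label
      rule <- "default"
    }
  } else {
    incl <- matched & roles == "NSCLC_inclusion"
    if (any(incl)) {
      predicted <- "NSCLC"
      rule <- paste0("nsclc_inclusion:", crit_names[which(incl)[1]])
    } else {
      predicted <- algorithm$default_label
      rule <- "default"
    }
  }
  list(predicted = predicted, matched_criteria = matched_criteria,
       decisive_rule = rule)
}

#' Classify a cohort
#'
#' Evaluates every algorithm criterion against each patient's claims inside
#' the per-patient evaluation window (`index_date` minus/plus
#' `eval_window`) and applies the classification policy. Deterministic
#' given inputs; claim-row order and duplicates never change the result.
#'
#' @param patients patient data.frame (`patient_id`, `index_date`).
#' @param claims claim lines for the cohort.
#' @param algorithm a `case_finding_algorithm`.
#' @param codelists registry from [read_codelists()].
#' @param quiet suppress the summary message.
#' @return data.frame: `patient_id`, `predicted`, `matched_criteria`
#'   (criteria names collapsed with `;`), `decisive_rule`.
#' @export
classify_cohort <- function(patients, claims, algorithm, codelists,
                            quiet = FALSE) {
  for (cr in algorithm$criteria)
    for (cp in cr$components) resolve_concept(cp, codelists)
  events <- claims_to_concepts(claims, codelists)
  ev_by_pt <- split(events[c("concept", "service_date")], events$patient_id)

  n <- nrow(patients)
  predicted <- character(n); matched <- character(n); rule <- character(n)
  crit_names <- vapply(algorithm$criteria, `[[`, character(1), "name")
  roles <- vapply(algorithm$criteria, `[[`, character(1), "role")
  comps <- lapply(algorithm$criteria, `[[`, "components")
  wins <- vapply(algorithm$criteria, function(cr)
    as.integer(cr$combo_window_days %||% 21L), integer(1))

  for (i in seq_len(n)) {
    idx <- as.integer(as.Date(patients$index_date[i]))
    w0 <- idx - algorithm$eval_window[1]
    w1 <- idx + algorithm$eval_window[2]
    ev <- ev_by_pt[[patients$patient_id[i]]]
    if (is.null(ev)) {
      concept_dates <- list()
    } else {
      d <- as.integer(ev$service_date)
      keep <- d >= w0 & d <= w1
      concept_dates <- split(d[keep], ev$concept[keep])
      concept_dates <- lapply(concept_dates, function(x) sort(unique(x)))
    }
    is_matched <- vapply(seq_along(comps), function(j) {
      dl <- concept_dates[comps[[j]]]
      if (any(vapply(dl, is.null, logical(1))) || any(lengths(dl) == 0L))
        return(FALSE)
      if (length(dl) == 1L) return(TRUE)
      w <- wins[j]
      anchors <- sort(unique(unlist(dl, use.names = FALSE)))
      for (a in anchors) {
        if (all(vapply(dl, function(x) any(x >= a & x <= a + w - 1L),
                       logical(1)))) return(TRUE)
      }
      FALSE
    }, logical(1))

    if (algorithm$policy == "exclusion_first" &&
        any(is_matched & roles == "SCLC_exclusion")) {
      predicted[i] <- "SCLC"
      rule[i] <- paste0("sclc_exclusion:",
                        crit_names[which(is_matched & roles == "SCLC_exclusion")[1]])
    } else if (any(is_matched & roles == "NSCLC_inclusion")) {
      predicted[i] <- "NSCLC"
      rule[i] <- paste0("nsclc_inclusion:",
                        crit_names[which(is_matched & roles == "NSCLC_inclusion")[1]])
    } else {
      predicted[i] <- algorithm$default_label
      rule[i] <- "default"
    }
    matched[i] <- paste(crit_names[is_matched], collapse = ";")
  }
  out <- data.frame(patient_id = patients$patient_id, predicted = predicted,
                    matched_criteria = matched, decisive_rule = rule,
                    stringsAsFactors = FALSE)
  if (!quiet) {
    tab <- table(factor(out$predicted, levels = c("NSCLC", "SCLC", "UNCLASSIFIED")))
    message(sprintf("%s: classified %d patients (NSCLC %d, SCLC %d, unclassified %d)",
                    algorithm$name, n, tab[["NSCLC"]], tab[["SCLC"]],
                    tab[["UNCLASSIFIED"]]))
  }
  out
}
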