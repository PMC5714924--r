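#' Read a concept code registry
#'
#' A code registry maps treatment/test concepts ("cisplatin", "pet_scan",
#' "lung_resection", ...) to the billing codes that identify them in claims:
#' a YAML mapping of concept name to a list of `{system, code}` entries.
#' The package bundles `concepts_synthetic.yaml`, a synthetic placeholder
#' registry; studies against real claims supply their own dictionaries.
#'
#' @param path YAML file path.
#' @return named list; each element a data.frame with `system`, `code`.
#' @export
read_codelists <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) {
    stop_casefindr("code registry '%s' is empty", path,
                   class = "casefindr_config_error")
  }
  out <- lapply(raw, function(entries) {
    df <- data.frame(
      system = vapply(entries, function(e) as.character(e$system), character(1)),
      code = vapply(entries, function(e) as.character(e$code), character(1)),
      stringsAsFactors = FALSE)
    bad <- setdiff(unique(df$system), CODE_SYSTEMS)
    if (length(bad) > 0L) {
      stop_casefindr("code registry '%s': unknown code system(s) %s", path,
                     paste(bad, collapse = ", "),
                     class = "casefindr_config_error")
    }
    df
  })
  if (anyDuplicated(names(out))) {
    stop_casefindr("code registry '%s': duplicated concept name(s)", path,
                   class = "casefindr_config_error")
  }
  out
}

#' Path to a bundled configuration file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists what is bundled.
#' @export
casefindr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "casefindr")))
  }
  path <- system.file("extdata", file, package = "casefindr")
  if (!nzchar(path)) {
    stop_casefindr("no bundled file '%s'", file, class = "casefindr_config_error")
  }
  path
}

resolve_concept <- function(concept, codelists) {
  cl <- codelists[[concept]]
  if (is.null(cl) || nrow(cl) == 0L) {
    stop_casefindr("concept '%s' is not in the code registry (or has no codes)",
                   concept, class = "casefindr_config_error")
  }
  cl
}

# One lookup table over the whole registry: (system, code) -> concept.
# Joining claims against this once is much cheaper than per-concept scans.
code_index <- function(codelists) {
  n <- vapply(codelists, nrow, integer(1))
  data.frame(
    code_system = unlist(lapply(codelists, `[[`, "system"), use.names = FALSE),
    code = unlist(lapply(codelists, `[[`, "code"), use.names = FALSE),
    concept = rep(names(codelists), n),
    stringsAsFactors = FALSE)
}

# Claims -> (concept, service_date) events for one or more patients.
claims_to_concepts <- function(claims, codelists) {
  idx <- code_index(codelists)
  key_claims <- paste(claims$code_system, claims$code, sep = "\r")
  key_idx <- paste(idx$code_system, idx$code, sep = "\r")
  hit <- match(key_claims, key_idx)
  keep <- !is.na(hit)
  data.frame(patient_id = claims$patient_id[keep],
             concept = idx$concept[hit[keep]],
             service_date = claims$service_date[keep],
             stringsAsFactors = FALSE)
}

#' Dates on which a concept appears in a patient's claims
#'
#' Membership matching: a concept "occurs" on every service date carrying
#' any of its codes inside the evaluation window. Drug and procedure
#' concepts are matched identically.
#'
#' @param claims claim lines for one patient.
#' @param concept concept name to look up.
#' @param codelists registry from [read_codelists()].
#' @param window_start,window_end evaluation window (inclusive).
#' @return sorted unique `Date` vector (possibly empty).
#' @export
match_concept <- function(claims, concept, codelists, window_start, window_end) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end)
  cl <- resolve_concept(concept, codelists)
  key_claims <- paste(claims$code_system, claims$code, sep = "\r")
  key_cl <- paste(cl$system, cl$code, sep = "\r")
  d <- claims$service_date[key_claims %in% key_cl]
  d <- d[d >= window_start & d <= window_end]
  sort(unique(d))
}

#' Test one criterion against a patient's claims
#'
#' A single-component criterion matches when its concept appears at least
#' once in the window. A combination regimen (2+ components) matches when
#' some anchor date starts a run of `combo_window_days` days — one treatment
#' cycle — containing at least one occurrence of every component, all inside
#' the evaluation window. Evidence records one qualifying date per component.
#'
#' @param claims claim lines for one patient.
#' @param criterion a criterion entry (list with `name`, `role`,
#'   `components`, and `combo_window_days` for combinations).
#' @inheritParams match_concept
#' @return list of class `criterion_match`: `name`, `role`, `matched`,
#'   `evidence` (data.frame of concept / service_date).
#' @export
detect_criterion <- function(claims, criterion, codelists,
                             window_start, window_end) {
  comp_dates <- lapply(criterion$components, match_concept,
                       claims = claims, codelists = codelists,
                       window_start = window_start, window_end = window_end)
  names(comp_dates) <- criterion$components
  k <- length(comp_dates)
  matched <- FALSE
  evidence <- data.frame(concept = character(0),
                         service_date = as.Date(character(0)),
                         stringsAsFactors = FALSE)
  if (k == 1L) {
    if (length(comp_dates[[1]]) > 0L) {
      matched <- TRUE
      evidence <- data.frame(concept = criterion$components,
                             service_date = comp_dates[[1]][1],
                             stringsAsFactors = FALSE)
    }
  } else if (all(lengths(comp_dates) > 0L)) {
    w <- as.integer(criterion$combo_window_days %||% 21)
    stopifnot(w >= 1L)
    # anchors need only range over observed component dates: shifting an
    # anchor right to the next observed date never loses a qualifying set
    anchors <- sort(unique(as.integer(do.call(c, unname(comp_dates)))))
    for (a in anchors) {
      picks <- lapply(comp_dates, function(d) {
        di <- as.integer(d)
        d[di >= a & di <= a + w - 1L][1]
      })
      if (!anyNA(unlist(lapply(picks, as.integer)))) {
        matched <- TRUE
        evidence <- data.frame(
          concept = names(picks),
          service_date = as.Date(unlist(lapply(picks, as.integer)),
                                 origin = "1970-01-01"),
          stringsAsFactors = FALSE)
        rownames(evidence) <- NULL
        break
      }
    }
  }
  structure(list(name = criterion$name, role = criterion$role,
                 matched = matched, evidence = evidence),
            class = "criterion_match")
}

#' Evaluate every criterion of a set against a patient's claims
#'
#' @param claims claim lines for one patient.
#' @param criteria list of criterion entries (e.g. `algorithm$criteria`).
#' @inheritParams match_concept
#' @return list of `criterion_match`, in criteria order.
#' @export
evaluate_all <- function(claims, criteria, codelists, window_start, window_end) {
  lapply(criteria, detect_criterion, claims = claims, codelists = codelists,
         window_start = window_start, window_end = window_end)
}

#' @export
print.criterion_match <- function(x, ...) {
  cat(sprintf("<criterion_match> %s [%s]: %s\n", x$name, x$role,
              if (x$matched) "matched" else "not matched"))
  if (x$matched) {
    cat(paste(sprintf("  %s @ %s", x$evidence$concept,
                      format(x$evidence$service_date)), collapse = "\n"), "\n")
  }
  invisible(x)
}
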