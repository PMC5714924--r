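# Shared fixtures, built in code.

mini_codelists <- function() {
  mk <- function(...) {
    e <- list(...)
    data.frame(system = vapply(e, `[[`, character(1), 1),
               code = vapply(e, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  list(cisplatin = mk(c("GPI", "CIS1"), c("HCPCS", "JCIS")),
       etoposide = mk(c("GPI", "ETO1")),
       irinotecan = mk(c("GPI", "IRI1")),
       carboplatin = mk(c("GPI", "CAR1")),
       paclitaxel = mk(c("GPI", "PAC1")),
       bevacizumab = mk(c("GPI", "BEV1")),
       topotecan = mk(c("GPI", "TOP1")),
       pet_scan = mk(c("CPT", "PET1"), c("HCPCS", "PET2")),
       lung_resection = mk(c("CPT", "RES1")))
}

claim_row <- function(pid, date, system, code) {
  data.frame(patient_id = pid, service_date = as.Date(date),
             code_system = system, code = code, stringsAsFactors = FALSE)
}

# claims for one patient: one row per (concept, date), using the concept's
# first registry code
concept_claims <- function(pid, concepts, dates, codelists = mini_codelists()) {
  do.call(rbind, Map(function(cc, d) {
    cl <- codelists[[cc]]
    claim_row(pid, d, cl$system[1], cl$code[1])
  }, concepts, as.list(as.Date(dates))))
}

criterion_def <- function(name, role, components, combo_window_days = 21L) {
  list(name = name, role = role, components = components,
       combo_window_days = combo_window_days)
}

# Brute-force oracle for combination-regimen detection: enumerate every
# combination of one observed date per component and accept if the spread
# fits inside the cycle window (all dates already window-filtered).
brute_force_combo <- function(component_dates, combo_window_days) {
  if (any(lengths(component_dates) == 0L)) return(FALSE)
  grids <- do.call(expand.grid, lapply(component_dates, as.integer))
  any(apply(grids, 1, function(r) max(r) - min(r) <= combo_window_days - 1L))
}

# Trapezoidal ROC area computed from first principles (threshold sweep),
# independent of the Mann-Whitney implementation.
trapezoid_auc <- function(scores, labels_pos) {
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(c(Inf, th), function(t) mean(scores[labels_pos] >= t), numeric(1))
  fpr <- vapply(c(Inf, th), function(t) mean(scores[!labels_pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

random_confusion_table <- function() {
  confusion_counts(tp = sample(1:500, 1), fp = sample(1:500, 1),
                   fn = sample(1:500, 1), tn = sample(1:500, 1))
}

shared_codelists <- function() {
  read_codelists(casefindr_example("concepts_synthetic.yaml"))
}
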