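test_that("the bundled case-finding algorithm matches its published structure", {
  cl <- shared_codelists()
  alg <- build_case_finding_algorithm(codelists = cl)
  roles <- vapply(alg$criteria, `[[`, character(1), "role")
  names_ <- vapply(alg$criteria, `[[`, character(1), "name")

  excl <- names_[roles == "SCLC_exclusion"]
  expect_length(excl, 9L)
  expect_true(all(c("Cisplatin and etoposide", "Topotecan", "Bendamustine",
                    "Cyclophosphamide, doxorubicin, and vincristine")
                  %in% excl))
  # single-agent taxanes and the like are control-only, not case-finding rows
  incl <- names_[roles == "NSCLC_inclusion"]
  expect_false(any(c("Paclitaxel", "Docetaxel", "Gemcitabine", "Etoposide",
                     "Vinorelbine", "Irinotecan", "Pemetrexed") %in% incl))
  expect_true(all(c("PET scan imaging", "Lung removal or resection surgery",
                    "Erlotinib", "Bevacizumab, carboplatin, and paclitaxel")
                  %in% incl))
  expect_equal(alg$policy, "exclusion_first")
})

test_that("the control algorithm is inclusion-only over the full guideline list", {
  cl <- shared_codelists()
  ctrl <- build_control_algorithm(codelists = cl)
  roles <- vapply(ctrl$criteria, `[[`, character(1), "role")
  names_ <- vapply(ctrl$criteria, `[[`, character(1), "name")
  expect_equal(ctrl$policy, "inclusion_only")
  expect_equal(sum(roles == "SCLC_exclusion"), 0L)
  expect_true(all(c("Pemetrexed", "Topotecan", "Paclitaxel",
                    "Cisplatin and etoposide") %in% names_))
  expect_gt(length(ctrl$criteria),
            length(build_case_finding_algorithm(codelists = cl)$criteria))
})

test_that("algorithms referencing unknown concepts fail at build time", {
  cl <- mini_codelists()
  raw <- yaml::read_yaml(casefindr_example("table1_case_finding.yaml"))
  expect_error(build_algorithm_from <- read_algorithm(
    casefindr_example("table1_case_finding.yaml"), codelists = cl),
    class = "casefindr_config_error")  # mini registry lacks most drugs
})

fake_match <- function(name, role, matched) {
  structure(list(name = name, role = role, matched = matched,
                 evidence = NULL), class = "criterion_match")
}

test_that("classification policy: exclusion precedence, inclusion, default", {
  alg <- list(name = "toy", policy = "exclusion_first", default_label = "SCLC",
              eval_window = c(90L, 90L),
              criteria = list(
                criterion_def("Carboplatin and etoposide", "SCLC_exclusion",
                              c("carboplatin", "etoposide")),
                criterion_def("PET scan imaging", "NSCLC_inclusion", "pet_scan")))
  class(alg) <- "case_finding_algorithm"

  both <- list(fake_match("Carboplatin and etoposide", "SCLC_exclusion", TRUE),
               fake_match("PET scan imaging", "NSCLC_inclusion", TRUE))
  r <- classify_patient(both, alg)
  expect_equal(r$predicted, "SCLC")
  expect_match(r$decisive_rule, "^sclc_exclusion:")

  pet_only <- list(fake_match("Carboplatin and etoposide", "SCLC_exclusion", FALSE),
                   fake_match("PET scan imaging", "NSCLC_inclusion", TRUE))
  expect_equal(classify_patient(pet_only, alg)$predicted, "NSCLC")

  none <- list(fake_match("Carboplatin and etoposide", "SCLC_exclusion", FALSE),
               fake_match("PET scan imaging", "NSCLC_inclusion", FALSE))
  r0 <- classify_patient(none, alg)
  expect_equal(r0$predicted, "SCLC")
  expect_equal(r0$decisive_rule, "default")

  expect_error(classify_patient(pet_only[1], alg),
               class = "casefindr_contract_error")
})

test_that("adding SCLC-regimen claims can only move labels toward SCLC", {
  cl <- shared_codelists()
  alg <- build_case_finding_algorithm(codelists = cl)
  co <- generate_cohort(synthetic_cohort_config(n_patients = 60, seed = 21), cl)
  before <- classify_cohort(co$patients, co$claims, alg, cl, quiet = TRUE)
  # give every patient a topotecan claim at index (an SCLC exclusion row)
  top <- co$patients
  extra <- data.frame(patient_id = top$patient_id,
                      service_date = top$index_date,
                      code_system = cl$topotecan$system[1],
                      code = cl$topotecan$code[1], stringsAsFactors = FALSE)
  after <- classify_cohort(co$patients, rbind(co$claims, extra), alg, cl,
                           quiet = TRUE)
  expect_true(all(after$predicted == "SCLC"))
  expect_false(any(before$predicted == "SCLC" & after$predicted == "NSCLC"))
})

test_that("cohort classification is deterministic and duplicate-insensitive", {
  cl <- shared_codelists()
  alg <- build_case_finding_algorithm(codelists = cl)
  co <- generate_cohort(synthetic_cohort_config(n_patients = 40, seed = 9), cl)
  a <- classify_cohort(co$patients, co$claims, alg, cl, quiet = TRUE)
  b <- classify_cohort(co$patients, co$claims[sample(nrow(co$claims)), ],
                       alg, cl, quiet = TRUE)
  d <- classify_cohort(co$patients, rbind(co$claims, co$claims), alg, cl,
                       quiet = TRUE)
  expect_identical(a, b)
  expect_identical(a, d)
  expect_equal(nrow(a), 40L)

  empty <- classify_cohort(co$patients[0, ], co$claims, alg, cl, quiet = TRUE)
  expect_equal(nrow(empty), 0L)
})

test_that("with no matching claims at all, every patient gets the default label", {
  cl <- shared_codelists()
  alg <- build_case_finding_algorithm(codelists = cl)
  co <- generate_cohort(synthetic_cohort_config(n_patients = 15, seed = 2), cl)
  res <- classify_cohort(co$patients, co$claims[0, ], alg, cl, quiet = TRUE)
  expect_true(all(res$predicted == "SCLC"))
  expect_true(all(res$decisive_rule == "default"))
})
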