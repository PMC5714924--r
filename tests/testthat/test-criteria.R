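test_that("concept matching is windowed, deduplicated set membership", {
  cl <- mini_codelists()
  idx <- as.Date("2015-01-01")
  claims <- rbind(claim_row("P1", idx + 5, "HCPCS", "PET2"),
                  claim_row("P1", idx + 5, "CPT", "PET1"),   # same day, other code
                  claim_row("P1", idx - 100, "CPT", "PET1")) # outside window
  expect_equal(match_concept(claims, "pet_scan", cl, idx - 90, idx + 90),
               idx + 5)
  expect_length(match_concept(claims, "pet_scan", cl, idx + 10, idx + 90), 0L)
  expect_error(match_concept(claims, "no_such_concept", cl, idx - 90, idx + 90),
               "no_such_concept", class = "casefindr_config_error")
})

test_that("combination criteria require co-occurrence within the cycle window", {
  cl <- mini_codelists()
  idx <- as.Date("2015-01-01")
  crit <- criterion_def("Cisplatin and etoposide", "SCLC_exclusion",
                        c("cisplatin", "etoposide"), 21L)

  near <- concept_claims("P1", c("cisplatin", "etoposide"), c(idx, idx + 2))
  m <- detect_criterion(near, crit, cl, idx - 90, idx + 90)
  expect_true(m$matched)
  expect_setequal(m$evidence$concept, c("cisplatin", "etoposide"))
  expect_setequal(as.integer(m$evidence$service_date),
                  as.integer(c(idx, idx + 2)))

  far <- concept_claims("P1", c("cisplatin", "etoposide"), c(idx, idx + 40))
  expect_false(detect_criterion(far, crit, cl, idx - 90, idx + 90)$matched)

  triple <- criterion_def("Bevacizumab, carboplatin, and paclitaxel",
                          "NSCLC_inclusion",
                          c("bevacizumab", "carboplatin", "paclitaxel"), 21L)
  claims3 <- concept_claims("P1", c("bevacizumab", "carboplatin", "paclitaxel"),
                            c(idx, idx + 7, idx + 14))
  expect_true(detect_criterion(claims3, triple, cl, idx - 90, idx + 90)$matched)
})

test_that("combination detection agrees with brute-force date enumeration", {
  cl <- mini_codelists()
  idx <- as.Date("2015-01-01")
  comps <- c("cisplatin", "etoposide", "irinotecan")
  set.seed(11)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    use <- comps[seq_len(k)]
    w <- sample(c(7L, 21L, 30L), 1)
    crit <- criterion_def("combo", "SCLC_exclusion", use, w)
    dates <- lapply(use, function(x) idx + sample(-80:80, sample(0:4, 1)))
    claims <- do.call(rbind, Map(function(cc, dd) {
      if (length(dd) == 0L) return(NULL)
      concept_claims("P1", rep(cc, length(dd)), dd)
    }, use, dates))
    if (is.null(claims)) claims <- concept_claims("P1", "topotecan", idx)[0, ]
    got <- detect_criterion(claims, crit, cl, idx - 90, idx + 90)$matched
    want <- brute_force_combo(dates, w)
    expect_identical(got, want)
  }
})

test_that("widening the evaluation window never unmatches a criterion", {
  cl <- mini_codelists()
  idx <- as.Date("2015-01-01")
  crit <- criterion_def("Cisplatin and etoposide", "SCLC_exclusion",
                        c("cisplatin", "etoposide"), 21L)
  set.seed(5)
  for (rep in 1:30) {
    claims <- concept_claims("P1",
                             sample(c("cisplatin", "etoposide"), 5, replace = TRUE),
                             idx + sample(-100:100, 5))
    widths <- c(10, 30, 60, 90, 120)
    res <- vapply(widths, function(w)
      detect_criterion(claims, crit, cl, idx - w, idx + w)$matched, logical(1))
    expect_true(all(diff(res) >= 0))
    # evidence always inside the window it was found in
    for (w in widths) {
      m <- detect_criterion(claims, crit, cl, idx - w, idx + w)
      if (m$matched) {
        expect_true(all(m$evidence$service_date >= idx - w &
                          m$evidence$service_date <= idx + w))
      }
    }
  }
})

test_that("evaluate_all preserves order, is deterministic, and ignores row order", {
  cl <- mini_codelists()
  idx <- as.Date("2015-01-01")
  criteria <- list(
    criterion_def("Topotecan", "SCLC_exclusion", "topotecan"),
    criterion_def("PET scan imaging", "NSCLC_inclusion", "pet_scan"),
    criterion_def("Carboplatin and paclitaxel", "NSCLC_inclusion",
                  c("carboplatin", "paclitaxel"), 21L))
  empty <- concept_claims("P1", "cisplatin", idx)[0, ]
  res0 <- evaluate_all(empty, criteria, cl, idx - 90, idx + 90)
  expect_false(any(vapply(res0, `[[`, logical(1), "matched")))

  claims <- concept_claims("P1", "pet_scan", idx + 3)
  res1 <- evaluate_all(claims, criteria, cl, idx - 90, idx + 90)
  expect_equal(vapply(res1, `[[`, character(1), "name"),
               vapply(criteria, `[[`, character(1), "name"))
  expect_equal(vapply(res1, `[[`, logical(1), "matched"),
               c(FALSE, TRUE, FALSE))

  big <- rbind(claims,
               concept_claims("P1", c("carboplatin", "paclitaxel"),
                              c(idx, idx + 5)))
  shuffled <- big[sample(nrow(big)), ]
  expect_identical(evaluate_all(big, criteria, cl, idx - 90, idx + 90),
                   evaluate_all(shuffled, criteria, cl, idx - 90, idx + 90))
})
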