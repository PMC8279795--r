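test_that("transition classification follows the discrepancy taxonomy", {
  expect_equal(classify_transition("NOT_APPLICABLE", "NONCOMPLIANT"),
               "NA_TO_NC")
  expect_equal(classify_transition("NOT_APPLICABLE", "COMPLIANT"), "NA_TO_CC")
  expect_equal(classify_transition("NONCOMPLIANT", "COMPLIANT"), "NC_TO_CC")
  expect_equal(classify_transition("COMPLIANT", "NONCOMPLIANT"), "CC_TO_NC")
  expect_equal(classify_transition("COMPLIANT", "COMPLIANT"), "NONE")
  expect_equal(classify_transition("EXCLUDED", "COMPLIANT"), "OTHER")
  expect_equal(classify_transition("NOT_APPLICABLE", "EXCLUDED"), "OTHER")
  expect_error(classify_transition("COMPLIANT", "MAYBE"), "unknown outcome")

  # the six categories partition all pairs: NONE iff equal
  for (a in outcome_levels()) for (b in outcome_levels()) {
    cat <- classify_transition(a, b)
    expect_true(cat %in% category_levels())
    expect_equal(cat == "NONE", a == b)
  }
})

test_that("performance rate omits excluded and not-applicable outcomes", {
  expect_equal(performance_rate(rep(c("COMPLIANT", "NONCOMPLIANT", "EXCLUDED",
                                      "NOT_APPLICABLE"), c(3, 1, 1, 5))), 0.75)
  expect_equal(performance_rate(rep("NONCOMPLIANT", 10)), 0)
  expect_true(is.na(performance_rate(rep("NOT_APPLICABLE", 7))))
})

test_that("net compliance change is the scope difference in rates, in points", {
  # 2 compliant / 2 noncompliant at origin; one flips to compliant with all
  # sources: 75% - 50% = +25 points
  paired <- make_paired(c("COMPLIANT>COMPLIANT" = 2,
                          "NONCOMPLIANT>NONCOMPLIANT" = 1,
                          "NONCOMPLIANT>COMPLIANT" = 1))
  expect_equal(compliance_change(paired, "cms165"), 25)

  # identical scopes: zero change
  same <- make_paired(c("COMPLIANT>COMPLIANT" = 4, "NONCOMPLIANT>NONCOMPLIANT" = 4))
  expect_equal(compliance_change(same, "cms165"), 0)

  # undefined origin rate is signalled, not zeroed
  na_side <- make_paired(c("NOT_APPLICABLE>COMPLIANT" = 3))
  expect_warning(cc <- compliance_change(na_side, "cms165"),
                 "origin-scope rate undefined")
  expect_true(is.na(cc))
})

test_that("swapping the scopes negates the net compliance change", {
  set.seed(99)
  for (i in 1:10) {
    counts <- setNames(rpois(4, 6) + 1,
                       c("COMPLIANT>COMPLIANT", "NONCOMPLIANT>NONCOMPLIANT",
                         "NONCOMPLIANT>COMPLIANT", "COMPLIANT>NONCOMPLIANT"))
    paired <- make_paired(counts)
    swapped <- paired
    swapped$origin_outcome <- paired$all_outcome
    swapped$all_outcome <- paired$origin_outcome
    expect_equal(compliance_change(swapped, "cms165"),
                 -compliance_change(paired, "cms165"))
  }
})

test_that("paired evaluation yields one result per patient and measure, monotone in eligibility", {
  pop <- deduplicate_documents(generate_population(small_config(seed = 31)))
  paired <- paired_evaluate(pop, CATALOG, PERIOD)
  expect_equal(nrow(paired), nrow(pop$patients) * length(CATALOG))
  # eligibility monotonicity: all-scope not-applicable forces origin too
  na_all <- paired$all_outcome == "NOT_APPLICABLE"
  expect_true(all(paired$origin_outcome[na_all] == "NOT_APPLICABLE"))
})

test_that("zero-fragmentation paired results are identical across scopes", {
  pop <- deduplicate_documents(generate_population(small_config(theta = 0,
                                                                seed = 8)))
  paired <- paired_evaluate(pop, CATALOG, PERIOD)
  expect_identical(paired$origin_outcome, paired$all_outcome)
})

test_that("a diagnosis known only externally makes the origin scope not applicable", {
  facs <- data.frame(facility_id = c("a1", "b1"),
                     org_id = c("orgA", "orgB"),
                     org_type = c("health_system", "ambulatory_practice"),
                     stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = "p1", sex = "female",
                    birth_date = as.Date("1958-01-01"),
                    race = "white", ethnicity = "non_hispanic",
                    originating_org = "orgA", stringsAsFactors = FALSE)
  ev <- rbind(
    make_events(c("encounter", "hba1c"), c("2018-02-01", "2018-06-01"),
                value = c(NA, 7.5), facility_id = "a1"),
    make_events(c("diabetes_dx", "encounter"), c("2017-07-01", "2017-07-01"),
                facility_id = "b1")
  )
  docs <- data.frame(doc_id = unique(ev$doc_id), patient_id = "p1",
                     facility_id = "a1",
                     service_date = as.Date("2018-02-01"),
                     received_at = as.POSIXct("2018-02-02", tz = "UTC"),
                     stringsAsFactors = FALSE)
  ev$doc_id <- docs$doc_id[1]
  pop <- fqm_population(pat, facs, docs, ev)
  paired <- paired_evaluate(pop, CATALOG, PERIOD)
  row <- paired[paired$measure_id == "cms122", ]
  expect_equal(row$origin_outcome, "NOT_APPLICABLE")
  expect_equal(row$all_outcome, "COMPLIANT")
})

test_that("aggregation conserves counts and flags patients with any change", {
  paired <- rbind(
    make_paired(c("COMPLIANT>COMPLIANT" = 4, "NONCOMPLIANT>COMPLIANT" = 2,
                  "NOT_APPLICABLE>NONCOMPLIANT" = 1,
                  "NOT_APPLICABLE>NOT_APPLICABLE" = 3), "cms130"),
    make_paired(c("NONCOMPLIANT>NONCOMPLIANT" = 5, "COMPLIANT>NONCOMPLIANT" = 1,
                  "EXCLUDED>COMPLIANT" = 1), "cms127")
  )
  paired$patient_id <- sprintf("p%03d", seq_len(nrow(paired)))
  facs <- data.frame(facility_id = "a1", org_id = "orgA",
                     org_type = "health_system", stringsAsFactors = FALSE)
  pats <- data.frame(patient_id = paired$patient_id, sex = "female",
                     birth_date = as.Date("1950-01-01"), race = "white",
                     ethnicity = "non_hispanic", originating_org = "orgA",
                     stringsAsFactors = FALSE)
  pop <- list(patients = pats, facilities = facs)
  report <- aggregate_report(paired, pop, n_resamples = 200, seed = 4)

  expect_equal(report$overall$applicable, 14)  # 17 rows minus 3 NA>NA
  expect_equal(report$overall$discrepancies, 5)
  expect_equal(report$overall$change_fraction, 5 / 14)
  per_m_disc <- vapply(report$per_measure, `[[`, numeric(1), "discrepancies")
  expect_equal(sum(per_m_disc), report$overall$discrepancies)
  # table rendering: totals row equals column sums
  tab <- render_table2(report)
  tot <- tab[tab$measure_id == "total", ]
  body <- tab[tab$measure_id != "total", ]
  for (col in c("applicable", "na_to_nc", "na_to_cc", "nc_to_cc", "cc_to_nc",
                "other")) {
    expect_equal(tot[[col]], sum(body[[col]]))
  }
  # patients: every row is a distinct patient here
  expect_equal(report$patients$with_applicable, 14)
  expect_equal(report$patients$changed, 5)
})
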