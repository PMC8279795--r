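test_that("completed-age computation handles birthdays and leap days", {
  expect_equal(age_on(as.Date("2000-01-01"), as.Date("2018-06-01")), 18L)
  expect_equal(age_on(as.Date("2000-07-01"), as.Date("2018-06-30")), 17L)
  expect_equal(age_on(as.Date("2000-02-29"), as.Date("2018-02-28")), 18L)
  expect_equal(age_on(as.Date("2000-02-29"), as.Date("2020-02-28")), 19L)
  expect_error(age_on(as.Date("2018-01-01"), as.Date("2017-12-31")),
               "precedes")
})

test_that("denominator logic gates on sex, age, conditions and encounters", {
  # pneumococcal measure: man of 68 with a period encounter is eligible
  p <- make_patient("1950-01-01", "male")
  ev <- make_events("encounter", "2018-03-01")
  expect_true(resolve_denominator(CATALOG$cms127, p, ev, PERIOD))
  # breast screening is restricted to women
  expect_false(resolve_denominator(CATALOG$cms125, p, ev, PERIOD))
  # diabetes measure requires a period encounter, not just the diagnosis
  p2 <- make_patient("1958-01-01", "female")
  ev2 <- make_events("diabetes_dx", "2017-05-01")
  expect_false(resolve_denominator(CATALOG$cms122, p2, ev2, PERIOD))
  ev3 <- make_events(c("diabetes_dx", "encounter"),
                     c("2017-05-01", "2018-02-01"))
  expect_true(resolve_denominator(CATALOG$cms122, p2, ev3, PERIOD))
})

test_that("exclusion windows distinguish ever-before from during-period", {
  woman <- make_patient("1960-01-01", "female")
  base <- make_events(c("encounter", "cervical_cytology"),
                      c("2018-02-01", "2017-06-01"))
  expect_false(resolve_exclusion(CATALOG$cms124, woman, base, PERIOD))
  with_hyst <- rbind(base, make_events("hysterectomy", "2005-01-01"))
  expect_true(resolve_exclusion(CATALOG$cms124, woman, with_hyst, PERIOD))
  expect_equal(evaluate_measure(CATALOG$cms124, woman, with_hyst, PERIOD),
               "EXCLUDED")
  # pregnancy excludes from the pediatric BMI measure only during the period
  teen <- make_patient("2003-06-01", "female")
  ev <- make_events(c("encounter", "pregnancy_dx"),
                    c("2018-03-01", "2018-05-01"))
  expect_equal(evaluate_measure(CATALOG$cms155, teen, ev, PERIOD), "EXCLUDED")
  ev_prior <- make_events(c("encounter", "pregnancy_dx"),
                          c("2018-03-01", "2016-05-01"))
  expect_equal(evaluate_measure(CATALOG$cms155, teen, ev_prior, PERIOD),
               "NONCOMPLIANT")
})

test_that("numerator windows and most-recent value predicates apply", {
  # colonoscopy seven years back satisfies the ten-year window
  p <- make_patient("1955-01-01", "male")
  ev <- make_events(c("encounter", "colonoscopy"),
                    c("2018-03-01", "2011-06-01"))
  expect_true(resolve_numerator(CATALOG$cms130, p, ev, PERIOD))
  expect_equal(evaluate_measure(CATALOG$cms130, p, ev, PERIOD), "COMPLIANT")
  # eleven years back does not
  ev$event_date[2] <- as.Date("2007-06-01")
  expect_equal(evaluate_measure(CATALOG$cms130, p, ev, PERIOD),
               "NONCOMPLIANT")

  # blood pressure control uses the most recent reading only
  hyp <- make_patient("1956-01-01", "female")
  ev_bp <- rbind(
    make_events(c("hypertension_dx", "encounter"), c("2017-01-15", "2018-03-01")),
    make_events("bp_reading", "2018-03-01", value = 150, value2 = 95),
    make_events("bp_reading", "2018-11-01", value = 132, value2 = 84)
  )
  expect_equal(evaluate_measure(CATALOG$cms165, hyp, ev_bp, PERIOD),
               "COMPLIANT")
  # reversed order in time: most recent reading uncontrolled
  ev_bp$event_date[3:4] <- as.Date(c("2018-11-01", "2018-03-01"))
  expect_equal(evaluate_measure(CATALOG$cms165, hyp, ev_bp, PERIOD),
               "NONCOMPLIANT")
})

test_that("inverse measures map the raw numerator to noncompliance", {
  # poor glycemic control: recent HbA1c of 9.5% is raw-met, hence noncompliant
  dia <- make_patient("1958-01-01", "female")
  ev <- rbind(
    make_events(c("diabetes_dx", "encounter"), c("2017-05-01", "2018-02-01")),
    make_events("hba1c", "2018-06-01", value = 9.5)
  )
  expect_equal(evaluate_measure(CATALOG$cms122, dia, ev, PERIOD),
               "NONCOMPLIANT")
  ev$value[3] <- 7.2
  expect_equal(evaluate_measure(CATALOG$cms122, dia, ev, PERIOD), "COMPLIANT")
  # no HbA1c at all also counts as poor control
  expect_equal(evaluate_measure(CATALOG$cms122, dia, ev[1:2, ], PERIOD),
               "NONCOMPLIANT")

  # high-risk medication order in an elder is noncompliant
  old <- make_patient("1948-01-01", "male")
  ev2 <- make_events(c("encounter", "high_risk_medication"),
                     c("2018-02-01", "2018-06-01"))
  expect_equal(evaluate_measure(CATALOG$cms156, old, ev2, PERIOD),
               "NONCOMPLIANT")
  expect_equal(evaluate_measure(CATALOG$cms156, old, ev2[1, ], PERIOD),
               "COMPLIANT")

  # ever-window numerator for pneumococcal vaccination
  ev3 <- make_events(c("encounter", "pneumococcal_vaccination"),
                     c("2018-02-01", "2010-05-05"))
  expect_equal(evaluate_measure(CATALOG$cms127, old, ev3, PERIOD), "COMPLIANT")
})

test_that("the episodic pharyngitis measure evaluates per episode", {
  kid <- make_patient("2008-01-15", "male")
  ep <- rbind(
    make_events("pharyngitis_dx", "2018-04-02"),
    make_events("antibiotic_medication", "2018-04-03"),
    make_events("strep_test", "2018-04-02")
  )
  expect_equal(evaluate_measure(CATALOG$cms146, kid, ep, PERIOD), "COMPLIANT")
  expect_equal(evaluate_measure(CATALOG$cms146, kid, ep[1:2, ], PERIOD),
               "NONCOMPLIANT")
  # diagnosis without an antibiotic is no episode at all
  expect_equal(evaluate_measure(CATALOG$cms146, kid, ep[1, , drop = FALSE],
                                PERIOD), "NOT_APPLICABLE")
  # a recent prior antibiotic excludes the episode
  ep_ex <- rbind(ep, make_events("antibiotic_medication", "2018-03-20"))
  expect_equal(evaluate_measure(CATALOG$cms146, kid, ep_ex, PERIOD),
               "EXCLUDED")
})

test_that("outcome precedence is strict and eligibility is monotone under added events", {
  # an excluded patient stays excluded even with a satisfied numerator
  woman <- make_patient("1960-01-01", "female")
  ev <- make_events(c("encounter", "mammogram", "bilateral_mastectomy"),
                    c("2018-02-01", "2018-04-01", "2001-01-01"))
  expect_equal(evaluate_measure(CATALOG$cms125, woman, ev, PERIOD), "EXCLUDED")

  # adding random events never turns an eligible patient not-applicable
  set.seed(303)
  pool <- REGISTRY$concept
  for (rep in 1:25) {
    mid <- sample(names(CATALOG), 1)
    p <- make_patient(sample(c("1950-03-01", "1962-07-20", "2009-05-05"), 1),
                      sample(c("female", "male"), 1))
    base_ev <- make_events(sample(pool, 6, replace = TRUE),
                           as.Date("2014-01-01") + sample(0:1800, 6),
                           value = round(runif(6, 1, 150)),
                           value2 = round(runif(6, 40, 110)))
    extra <- make_events(sample(pool, 4, replace = TRUE),
                         as.Date("2014-01-01") + sample(0:1800, 4),
                         value = round(runif(4, 1, 150)),
                         value2 = round(runif(4, 40, 110)))
    if (resolve_denominator(CATALOG[[mid]], p, base_ev, PERIOD)) {
      expect_true(resolve_denominator(CATALOG[[mid]], p,
                                      rbind(base_ev, extra), PERIOD))
    }
    out <- evaluate_measure(CATALOG[[mid]], p, base_ev, PERIOD)
    if (out != "NOT_APPLICABLE") {
      expect_true(evaluate_measure(CATALOG[[mid]], p, rbind(base_ev, extra),
                                   PERIOD) != "NOT_APPLICABLE")
    }
  }
})

test_that("catalog loading validates concepts and age ranges", {
  expect_s3_class(CATALOG, "fqm_catalog")
  expect_length(CATALOG, 14)
  expect_true(all(c("cms122", "cms146", "cms74") %in% names(CATALOG)))
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("measures:",
               "  - id: bogus",
               "    age: {min: 0, max: 10}",
               "    numerator:",
               "      - {concepts: [unicorn_scan], window: {type: mp}}"), bad)
  expect_error(measure_catalog(bad), "unregistered concept")
})
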