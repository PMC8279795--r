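# Independent brute-force oracles. These re-derive expected results by
# naive per-criterion scans with hand-written window dates for the 2018
# calendar-year period, deliberately sharing no code with the package
# internals.

D <- function(x) as.Date(x)
MP_LO <- D("2018-01-01")
MP_HI <- D("2018-12-31")
MP_MID <- D("2018-07-02")  # 2018-01-01 + floor(364 / 2)

o_has <- function(ev, concepts, lo = D("0001-01-01"), hi = MP_HI) {
  any(ev$concept %in% concepts & ev$event_date >= lo & ev$event_date <= hi)
}

o_latest <- function(ev, concept, lo, hi) {
  r <- ev[ev$concept == concept & ev$event_date >= lo & ev$event_date <= hi, ]
  if (nrow(r) == 0) return(NULL)
  r <- r[order(r$event_date, r$value, r$value2), ]
  r[nrow(r), ]
}

o_age <- function(birth, anchor = MP_HI) {
  by <- as.integer(format(birth, "%Y"))
  bm <- as.integer(format(birth, "%m"))
  bd <- as.integer(format(birth, "%d"))
  ay <- as.integer(format(anchor, "%Y"))
  bday_in <- function(y) {
    d <- bd
    leap <- (y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0
    if (bm == 2 && bd == 29 && !leap) d <- 28
    D(sprintf("%04d-%02d-%02d", y, bm, d))
  }
  k <- ay - by
  if (bday_in(ay) > anchor) k <- k - 1
  k
}

# Diabetes denominator shared by cms122/131/123/134.
o_diabetic_denom <- function(patient, ev) {
  age <- o_age(patient$birth_date)
  age >= 18 && age <= 75 &&
    o_has(ev, "diabetes_dx", D("2016-12-31"), MP_HI) &&
    o_has(ev, "encounter", MP_LO, MP_HI)
}

oracle_evaluate <- function(measure_id, patient, ev) {
  age <- o_age(patient$birth_date)
  finish <- function(raw, inverse = FALSE) {
    if (inverse) raw <- !raw
    if (raw) "COMPLIANT" else "NONCOMPLIANT"
  }
  switch(measure_id,
    cms122 = {
      if (!o_diabetic_denom(patient, ev)) return("NOT_APPLICABLE")
      if (o_has(ev, "hospice_care", MP_LO, MP_HI)) return("EXCLUDED")
      last <- o_latest(ev, "hba1c", MP_LO, MP_HI)
      raw <- is.null(last) || last$value > 9.0
      finish(raw, inverse = TRUE)
    },
    cms131 = {
      if (!o_diabetic_denom(patient, ev)) return("NOT_APPLICABLE")
      if (o_has(ev, "hospice_care", MP_LO, MP_HI)) return("EXCLUDED")
      finish(o_has(ev, "retinal_exam", D("2016-12-31"), MP_HI))
    },
    cms123 = {
      if (!o_diabetic_denom(patient, ev)) return("NOT_APPLICABLE")
      if (o_has(ev, "hospice_care", MP_LO, MP_HI)) return("EXCLUDED")
      finish(o_has(ev, "foot_exam", MP_LO, MP_HI))
    },
    cms134 = {
      if (!o_diabetic_denom(patient, ev)) return("NOT_APPLICABLE")
      if (o_has(ev, "hospice_care", MP_LO, MP_HI)) return("EXCLUDED")
      finish(o_has(ev, "nephropathy_screening", MP_LO, MP_HI) ||
               o_has(ev, "ace_arb_medication", MP_LO, MP_HI) ||
               o_has(ev, "nephropathy_dx", MP_LO, MP_HI))
    },
    cms165 = {
      if (age < 18 || age > 85 ||
          !o_has(ev, "hypertension_dx", D("0001-01-01"), MP_MID) ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      if (o_has(ev, "esrd_dx") || o_has(ev, "pregnancy_dx", MP_LO, MP_HI)) {
        return("EXCLUDED")
      }
      last <- o_latest(ev, "bp_reading", MP_LO, MP_HI)
      finish(!is.null(last) && last$value < 140 && last$value2 < 90)
    },
    cms125 = {
      if (patient$sex != "female" || age < 51 || age > 74 ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      if (o_has(ev, "bilateral_mastectomy")) return("EXCLUDED")
      finish(o_has(ev, "mammogram", D("2016-09-30"), MP_HI))
    },
    cms124 = {
      if (patient$sex != "female" || age < 23 || age > 64 ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      if (o_has(ev, "hysterectomy")) return("EXCLUDED")
      raw <- o_has(ev, "cervical_cytology", D("2015-12-31"), MP_HI) ||
        (age >= 30 && o_has(ev, "hpv_test", D("2013-12-31"), MP_HI))
      finish(raw)
    },
    cms130 = {
      if (age < 50 || age > 75 ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      if (o_has(ev, c("total_colectomy", "colorectal_cancer_dx"))) {
        return("EXCLUDED")
      }
      finish(o_has(ev, "fobt", MP_LO, MP_HI) ||
               o_has(ev, "sigmoidoscopy", D("2013-12-31"), MP_HI) ||
               o_has(ev, "colonoscopy", D("2008-12-31"), MP_HI))
    },
    cms127 = {
      if (age < 65 || !o_has(ev, "encounter", MP_LO, MP_HI)) {
        return("NOT_APPLICABLE")
      }
      finish(o_has(ev, "pneumococcal_vaccination"))
    },
    cms153 = {
      if (patient$sex != "female" || age < 16 || age > 24 ||
          !o_has(ev, "sexual_activity_marker", MP_LO, MP_HI) ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      finish(o_has(ev, "chlamydia_test", MP_LO, MP_HI))
    },
    cms155 = {
      if (age < 3 || age > 17 ||
          !o_has(ev, "encounter", MP_LO, MP_HI)) return("NOT_APPLICABLE")
      if (o_has(ev, "pregnancy_dx", MP_LO, MP_HI)) return("EXCLUDED")
      finish(o_has(ev, "bmi_percentile", MP_LO, MP_HI))
    },
    cms146 = {
      if (age < 3 || age > 18) return("NOT_APPLICABLE")
      dx <- sort(unique(ev$event_date[ev$concept == "pharyngitis_dx" &
                                        ev$event_date >= MP_LO &
                                        ev$event_date <= MP_HI]))
      abx <- ev$event_date[ev$concept == "antibiotic_medication"]
      tst <- ev$event_date[ev$concept == "strep_test"]
      episodes <- dx[vapply(dx, function(d)
        any(abx >= d & abx <= d + 3), logical(1))]
      if (length(episodes) == 0) return("NOT_APPLICABLE")
      qualifying <- episodes[vapply(episodes, function(d)
        !any(abx >= d - 30 & abx <= d - 1), logical(1))]
      if (length(qualifying) == 0) return("EXCLUDED")
      tested <- vapply(qualifying, function(d)
        any(tst >= d - 3 & tst <= d + 3), logical(1))
      if (all(tested)) "COMPLIANT" else "NONCOMPLIANT"
    },
    cms156 = {
      if (age < 65 || !o_has(ev, "encounter", MP_LO, MP_HI)) {
        return("NOT_APPLICABLE")
      }
      if (o_has(ev, "hospice_care", MP_LO, MP_HI)) return("EXCLUDED")
      finish(o_has(ev, "high_risk_medication", MP_LO, MP_HI), inverse = TRUE)
    },
    cms74 = {
      if (age < 0 || age > 20 || !o_has(ev, "encounter", MP_LO, MP_HI)) {
        return("NOT_APPLICABLE")
      }
      finish(o_has(ev, "fluoride_varnish", MP_LO, MP_HI))
    },
    stop("unknown measure ", measure_id)
  )
}

# Group-by-max deduplication oracle.
oracle_dedup <- function(documents) {
  key <- paste(documents$patient_id, documents$facility_id,
               documents$service_date)
  kept <- lapply(split(seq_len(nrow(documents)), key), function(i) {
    i[which.max(as.numeric(documents$received_at[i]))]
  })
  out <- documents[sort(unlist(kept)), ]
  rownames(out) <- NULL
  out
}

# Month-count facility-activity oracle.
oracle_activity <- function(counts_matrix) {
  pass <- character(0)
  for (f in rownames(counts_matrix)) {
    months_ok <- 0
    for (m in 1:12) if (counts_matrix[f, m] >= 100) months_ok <- months_ok + 1
    if (months_ok > 6) pass <- c(pass, f)
  }
  pass
}

# Exact null distribution of the symmetry statistic by enumerating every
# per-pair direction split (equivalent to the 2^d sign assignments, with
# binomial weights), for tables with few discordant units.
oracle_exact_symmetry_p <- function(tab) {
  m <- as.matrix(tab)
  k <- nrow(m)
  totals <- c()
  obs <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- m[i, j] + m[j, i]
      if (s > 0) {
        totals <- c(totals, s)
        obs <- obs + (m[i, j] - m[j, i])^2 / s
      }
    }
  }
  if (length(totals) == 0) return(1)
  grids <- lapply(totals, function(s) 0:s)
  combos <- expand.grid(grids)
  p_total <- 0
  for (r in seq_len(nrow(combos))) {
    ks <- as.numeric(combos[r, ])
    stat <- sum((2 * ks - totals)^2 / totals)
    if (stat >= obs - 1e-12) {
      p_total <- p_total + prod(stats::dbinom(ks, totals, 0.5))
    }
  }
  min(p_total, 1)
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
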