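# Seeded synthetic multi-facility clinical data generator.
#
# The generator emulates the fragmentation structure of a statewide health
# information exchange: patients are sampled per organization (health
# systems and ambulatory practices), accrue coded clinical events during a
# measurement period (plus a lookback horizon for historical screenings),
# and each clinical fact is recorded either at the patient's originating
# organization or at an external facility with a tunable fragmentation
# probability. Events are bundled into per-(facility, service date)
# document records, with optional duplicate documents to exercise
# deduplication.

#' Generator configuration
#'
#' Defaults emulate the study conditions of a statewide HIE sample: 21
#' health systems and 32 ambulatory practices, 100 patients sampled per
#' organization, a 2018 calendar-year measurement period, demographics per
#' organization type (57.0%/61.3% female, age bands skewing older in health
#' systems), roughly 20 clinical documents per patient, 79% of patients
#' using more than one facility, and an overall external-record fraction of
#' about 46%.
#'
#' @param n_health_systems,n_ambulatory_practices Number of organizations of
#'   each type.
#' @param patients_per_org Patients sampled per organization.
#' @param period A \code{\link{measurement_period}}.
#' @param theta Fragmentation rate: probability that a clinical fact of a
#'   multi-facility patient is recorded at a non-originating facility.
#'   \code{theta = 0} forces every event to the originating organization.
#' @param multi_facility_rate Probability that a patient uses any facility
#'   outside the originating organization at all (1 makes \code{theta} the
#'   unconditional per-event external probability). The default pair
#'   \code{0.464/0.79} and \code{0.79} yields ~46% external records over
#'   ~79% multi-facility patients.
#' @param condition_prevalences Named probabilities of chronic conditions
#'   and exclusion states among the age/sex-eligible.
#' @param care_probabilities Named per-eligible-patient probabilities of
#'   preventive/monitoring services.
#' @param event_rates Named yearly rates for repeated observations (HbA1c
#'   tests for diabetic patients, blood-pressure readings for hypertensive
#'   patients).
#' @param mean_encounters Mean routine-encounter count per patient by
#'   organization type (a patient always has at least one).
#' @param demographic_mix Per-organization-type sex/age/race/ethnicity
#'   weights.
#' @param facilities_per_health_system,facilities_per_practice Facilities
#'   per organization (origin scope is the organization, so multi-facility
#'   health systems make within-organization sharing visible).
#' @param duplicate_rate Probability a document is emitted twice with a
#'   later receipt timestamp.
#' @param lookback_years Lookback horizon before the period start; no
#'   generated event predates it.
#' @param seed Integer seed; identical configurations generate identical
#'   populations.
#' @return An object of class \code{fqm_config}.
#' @export
generator_config <- function(n_health_systems = 21,
                             n_ambulatory_practices = 32,
                             patients_per_org = 100,
                             period = measurement_period(),
                             theta = 0.464 / 0.79,
                             multi_facility_rate = 0.79,
                             condition_prevalences = NULL,
                             care_probabilities = NULL,
                             event_rates = NULL,
                             mean_encounters = NULL,
                             demographic_mix = NULL,
                             facilities_per_health_system = 3,
                             facilities_per_practice = 1,
                             duplicate_rate = 0.05,
                             lookback_years = 10,
                             seed = 1L) {
  prev <- list(diabetes = 0.12, hypertension = 0.25, pharyngitis = 0.25,
               sexual_activity = 0.40, pregnancy = 0.05, esrd = 0.04,
               hospice = 0.02, nephropathy = 0.05, colorectal_cancer = 0.02,
               total_colectomy = 0.01, hysterectomy = 0.08,
               bilateral_mastectomy = 0.02)
  prev[names(condition_prevalences)] <- condition_prevalences
  care <- list(mammogram = 0.70, cervical_cytology = 0.60, hpv_test = 0.30,
               colonoscopy = 0.45, sigmoidoscopy = 0.08, fobt = 0.15,
               pneumococcal_vaccination = 0.60, retinal_exam = 0.55,
               foot_exam = 0.60, nephropathy_screening = 0.45,
               ace_arb_medication = 0.40, chlamydia_test = 0.50,
               bmi_percentile = 0.55, fluoride_varnish = 0.30,
               high_risk_medication = 0.15,
               antibiotic_after_pharyngitis = 0.85, strep_test = 0.70)
  care[names(care_probabilities)] <- care_probabilities
  rates <- list(hba1c = 2, bp_reading = 3)
  rates[names(event_rates)] <- event_rates
  menc <- c(health_system = 19.3, ambulatory_practice = 17.9)
  if (!is.null(mean_encounters)) menc[names(mean_encounters)] <- mean_encounters
  mix <- demographic_mix %||% list(
    health_system = list(
      female = 0.570,
      age_bands = c(`0-4` = 0.075, `5-17` = 0.094, `18-64` = 0.485,
                    `65+` = 0.346),
      race = c(white = 0.849, black = 0.043, other = 0.108),
      ethnicity = c(non_hispanic = 0.905, hispanic = 0.095)
    ),
    ambulatory_practice = list(
      female = 0.613,
      age_bands = c(`0-4` = 0.058, `5-17` = 0.127, `18-64` = 0.573,
                    `65+` = 0.242),
      race = c(white = 0.768, black = 0.067, other = 0.166),
      ethnicity = c(non_hispanic = 0.928, hispanic = 0.072)
    )
  )
  cfg <- structure(
    list(n_health_systems = n_health_systems,
         n_ambulatory_practices = n_ambulatory_practices,
         patients_per_org = patients_per_org,
         period = period,
         theta = theta,
         multi_facility_rate = multi_facility_rate,
         condition_prevalences = prev,
         care_probabilities = care,
         event_rates = rates,
         mean_encounters = menc,
         demographic_mix = mix,
         facilities_per_health_system = facilities_per_health_system,
         facilities_per_practice = facilities_per_practice,
         duplicate_rate = duplicate_rate,
         lookback_years = lookback_years,
         seed = as.integer(seed)),
    class = "fqm_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot_prob(cfg$theta, "theta")
  stopifnot_prob(cfg$multi_facility_rate, "multi_facility_rate")
  stopifnot_prob(cfg$duplicate_rate, "duplicate_rate")
  stopifnot_prob(unlist(cfg$condition_prevalences), "condition prevalences")
  stopifnot_prob(unlist(cfg$care_probabilities), "care probabilities")
  n_orgs <- cfg$n_health_systems + cfg$n_ambulatory_practices
  if (n_orgs < 1) stop("at least one organization is required")
  if (cfg$n_health_systems < 0 || cfg$n_ambulatory_practices < 0) {
    stop("organization counts must be non-negative")
  }
  stopifnot_count(cfg$patients_per_org, "patients_per_org")
  if (cfg$theta > 0 && n_orgs < 2) {
    stop("theta > 0 requires at least two organizations to host external events")
  }
  if (!inherits(cfg$period, "fqm_period")) {
    stop("period must be a measurement_period()")
  }
  cfg
}

#' @export
print.fqm_config <- function(x, ...) {
  cat("Synthetic population generator configuration\n")
  cat(sprintf("  organizations: %d health systems + %d ambulatory practices\n",
              x$n_health_systems, x$n_ambulatory_practices))
  cat(sprintf("  patients/org:  %d\n", x$patients_per_org))
  cat(sprintf("  period:        %s to %s (lookback %d y)\n",
              x$period$start, x$period$end, x$lookback_years))
  cat(sprintf("  fragmentation: theta = %.3f, multi-facility rate = %.2f\n",
              x$theta, x$multi_facility_rate))
  cat(sprintf("  duplicates:    %.2f, seed %d\n", x$duplicate_rate, x$seed))
  invisible(x)
}

#' Study-emulation default configuration
#'
#' Returns the generator configuration whose expected outputs approximate
#' the study marginals: overall female fraction near 59.6%, Table-1 age
#' bands by organization type, roughly 20 deduplicated documents per
#' patient, ~46% of records external and ~79% of patients multi-facility.
#' These are approximate targets of a calibrated simulation, not
#' guarantees.
#'
#' @param ... Overrides passed to \code{\link{generator_config}}.
#' @return An \code{fqm_config}.
#' @export
emulate_study_defaults <- function(...) generator_config(...)

runif_date_int <- function(n, lo, hi) {
  lo <- pmin(lo, hi)
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Generate a synthetic population
#'
#' Deterministic for a given configuration (including its seed). Per
#' patient the generator draws demographics, chronic conditions per
#' prevalence, then clinical events per the care probabilities with dates
#' inside the measurement period or its lookback horizon; each event is
#' assigned to the originating organization with probability
#' \code{1 - theta} (for multi-facility patients) or to a uniformly chosen
#' external facility; an encounter is emitted alongside each clinical fact
#' at its facility and date; events are bundled into document records per
#' (facility, service date), and duplicate documents are injected per
#' \code{duplicate_rate} with later receipt timestamps.
#'
#' @param config An \code{\link{generator_config}}.
#' @return An \code{\link{fqm_population}} (documents include any injected
#'   duplicates; run \code{\link{deduplicate_documents}} before analysis).
#' @export
generate_population <- function(config) {
  config <- validate_config(config)
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  ps <- as.integer(cfg$period$start)
  pe <- as.integer(cfg$period$end)
  mid <- as.integer(cfg$period$mid)
  lb <- as.integer(shift_years(cfg$period$start, -cfg$lookback_years))

  ## -- organizations and facilities ---------------------------------------
  org_id <- c(sprintf("hs%02d", seq_len(cfg$n_health_systems)),
              sprintf("ap%02d", seq_len(cfg$n_ambulatory_practices)))
  org_type <- rep(ORG_TYPES, c(cfg$n_health_systems, cfg$n_ambulatory_practices))
  nfac <- ifelse(org_type == "health_system",
                 cfg$facilities_per_health_system, cfg$facilities_per_practice)
  facilities <- data.frame(
    facility_id = unlist(mapply(function(o, k) sprintf("%s_f%d", o, seq_len(k)),
                                org_id, nfac, SIMPLIFY = FALSE), use.names = FALSE),
    org_id = rep(org_id, nfac),
    org_type = rep(org_type, nfac),
    stringsAsFactors = FALSE
  )

  ## -- patients ------------------------------------------------------------
  n_pat <- length(org_id) * cfg$patients_per_org
  p_org <- rep(org_id, each = cfg$patients_per_org)
  p_orgtype <- rep(org_type, each = cfg$patients_per_org)
  mixes <- cfg$demographic_mix
  sex <- age <- race <- ethnicity <- rep(NA_character_, n_pat)
  age_years <- numeric(n_pat)
  band_lims <- list(`0-4` = c(1, 5), `5-17` = c(5, 18),
                    `18-64` = c(18, 65), `65+` = c(65, 95))
  for (ot in ORG_TYPES) {
    i <- which(p_orgtype == ot)
    mx <- mixes[[ot]]
    sex[i] <- ifelse(stats::runif(length(i)) < mx$female, "female", "male")
    bands <- sample(names(mx$age_bands), length(i), replace = TRUE,
                    prob = mx$age_bands)
    lo <- vapply(band_lims[bands], `[`, numeric(1), 1)
    hi <- vapply(band_lims[bands], `[`, numeric(1), 2)
    age_years[i] <- stats::runif(length(i), lo, hi)
    race[i] <- sample(names(mx$race), length(i), replace = TRUE, prob = mx$race)
    ethnicity[i] <- sample(names(mx$ethnicity), length(i), replace = TRUE,
                           prob = mx$ethnicity)
  }
  birth <- pe - as.integer(round(age_years * 365.25))
  patients <- data.frame(
    patient_id = sprintf("p%05d", seq_len(n_pat)),
    sex = sex,
    birth_date = as.Date(birth, origin = "1970-01-01"),
    race = race,
    ethnicity = ethnicity,
    originating_org = p_org,
    stringsAsFactors = FALSE
  )
  agec <- age_on(patients$birth_date, cfg$period$end)

  ## -- conditions ----------------------------------------------------------
  prev <- cfg$condition_prevalences
  draw <- function(mask, p) mask & stats::runif(n_pat) < p
  has <- list(
    diabetes = draw(agec >= 18 & agec <= 75, prev$diabetes),
    hypertension = draw(agec >= 18 & agec <= 85, prev$hypertension),
    pharyngitis = draw(agec >= 3 & agec <= 18, prev$pharyngitis),
    sexual_activity = draw(sex == "female" & agec >= 16 & agec <= 24,
                           prev$sexual_activity),
    pregnancy = draw(sex == "female" & agec >= 16 & agec <= 45, prev$pregnancy),
    colorectal_cancer = draw(agec >= 50 & agec <= 75, prev$colorectal_cancer),
    total_colectomy = draw(agec >= 50 & agec <= 75, prev$total_colectomy),
    hysterectomy = draw(sex == "female" & agec >= 30, prev$hysterectomy),
    bilateral_mastectomy = draw(sex == "female" & agec >= 50,
                                prev$bilateral_mastectomy),
    hospice = draw(agec >= 70, prev$hospice)
  )
  has$esrd <- draw(has$hypertension, prev$esrd)
  has$nephropathy <- draw(has$diabetes, prev$nephropathy)

  ## -- clinical events -----------------------------------------------------
  acc <- new.env(parent = emptyenv())
  acc$pidx <- acc$date <- acc$value <- acc$value2 <- list()
  acc$concept <- list()
  k <- 0L
  emit <- function(pidx, concept, dates, value = NA_real_, value2 = NA_real_) {
    if (length(pidx) == 0) return(invisible())
    k <<- k + 1L
    acc$pidx[[k]] <- as.integer(pidx)
    acc$concept[[k]] <- rep_len(concept, length(pidx))
    # dates never precede the lookback horizon or the first birthday
    acc$date[[k]] <- pmax(as.integer(dates), lb, birth[pidx] + 365L)
    acc$value[[k]] <- rep_len(as.numeric(value), length(pidx))
    acc$value2[[k]] <- rep_len(as.numeric(value2), length(pidx))
    invisible()
  }
  emit_bernoulli <- function(mask, concept, p, lo, hi) {
    i <- which(mask & stats::runif(n_pat) < p)
    emit(i, concept, runif_date_int(length(i), lo, hi))
  }
  care <- cfg$care_probabilities

  # routine encounters (every patient has at least one)
  n_enc <- 1L + stats::rpois(n_pat, pmax(cfg$mean_encounters[p_orgtype] - 1, 0))
  enc_idx <- rep(seq_len(n_pat), n_enc)
  emit(enc_idx, "encounter", runif_date_int(length(enc_idx), ps, pe))

  # condition diagnoses and exclusion states
  emit(which(has$diabetes), "diabetes_dx",
       runif_date_int(sum(has$diabetes), as.integer(shift_years(cfg$period$end, -2)), pe))
  emit(which(has$hypertension), "hypertension_dx",
       runif_date_int(sum(has$hypertension), as.integer(shift_years(cfg$period$mid, -2)), mid))
  emit(which(has$nephropathy), "nephropathy_dx",
       runif_date_int(sum(has$nephropathy), ps, pe))
  emit(which(has$pregnancy), "pregnancy_dx",
       runif_date_int(sum(has$pregnancy), ps, pe))
  emit(which(has$esrd), "esrd_dx",
       runif_date_int(sum(has$esrd), as.integer(shift_years(cfg$period$end, -5)), pe))
  emit(which(has$hospice), "hospice_care",
       runif_date_int(sum(has$hospice), ps, pe))
  emit(which(has$colorectal_cancer), "colorectal_cancer_dx",
       runif_date_int(sum(has$colorectal_cancer), lb, pe))
  emit(which(has$total_colectomy), "total_colectomy",
       runif_date_int(sum(has$total_colectomy), lb, pe))
  emit(which(has$hysterectomy), "hysterectomy",
       runif_date_int(sum(has$hysterectomy), lb, pe))
  emit(which(has$bilateral_mastectomy), "bilateral_mastectomy",
       runif_date_int(sum(has$bilateral_mastectomy), lb, pe))
  emit(which(has$sexual_activity), "sexual_activity_marker",
       runif_date_int(sum(has$sexual_activity), ps, pe))

  # pharyngitis episodes: diagnosis, antibiotic within 3 days, possible
  # recent prior antibiotic (episode exclusion), possible strep test
  ph <- which(has$pharyngitis)
  n_ep <- 1L + stats::rpois(length(ph), 0.3)
  ep_p <- rep(ph, n_ep)
  ep_d <- runif_date_int(length(ep_p), ps, pe - 3L)
  emit(ep_p, "pharyngitis_dx", ep_d)
  ab <- stats::runif(length(ep_p)) < care$antibiotic_after_pharyngitis
  emit(ep_p[ab], "antibiotic_medication",
       ep_d[ab] + sample(0:3, sum(ab), replace = TRUE))
  pr <- stats::runif(length(ep_p)) < 0.08
  emit(ep_p[pr], "antibiotic_medication",
       ep_d[pr] - sample(5:25, sum(pr), replace = TRUE))
  st <- stats::runif(length(ep_p)) < care$strep_test
  emit(ep_p[st], "strep_test", ep_d[st] + sample(-3:3, sum(st), replace = TRUE))

  # preventive screenings: draw dates over a clinically plausible span, so
  # that measure window arithmetic (not generation) decides compliance
  m36 <- as.integer(shift_months(cfg$period$end, -36))
  m18 <- as.integer(shift_months(cfg$period$end, -18))
  y4 <- as.integer(shift_years(cfg$period$end, -4))
  y6 <- as.integer(shift_years(cfg$period$end, -6))
  emit_bernoulli(sex == "female" & agec >= 50 & agec <= 74, "mammogram",
                 care$mammogram, m36, pe)
  emit_bernoulli(sex == "female" & agec >= 23 & agec <= 64, "cervical_cytology",
                 care$cervical_cytology, y4, pe)
  emit_bernoulli(sex == "female" & agec >= 30 & agec <= 64, "hpv_test",
                 care$hpv_test, y6, pe)
  emit_bernoulli(agec >= 50 & agec <= 75, "colonoscopy", care$colonoscopy, lb, pe)
  emit_bernoulli(agec >= 50 & agec <= 75, "sigmoidoscopy", care$sigmoidoscopy,
                 y6, pe)
  emit_bernoulli(agec >= 50 & agec <= 75, "fobt", care$fobt, m18, pe)
  emit_bernoulli(agec >= 65, "pneumococcal_vaccination",
                 care$pneumococcal_vaccination, lb, pe)
  emit_bernoulli(has$diabetes, "retinal_exam", care$retinal_exam,
                 as.integer(shift_months(cfg$period$end, -30)), pe)
  emit_bernoulli(has$diabetes, "foot_exam", care$foot_exam,
                 as.integer(shift_months(cfg$period$end, -15)), pe)
  emit_bernoulli(has$diabetes, "nephropathy_screening",
                 care$nephropathy_screening,
                 as.integer(shift_months(cfg$period$end, -15)), pe)
  emit_bernoulli(has$diabetes, "ace_arb_medication", care$ace_arb_medication,
                 ps, pe)
  emit_bernoulli(has$sexual_activity, "chlamydia_test", care$chlamydia_test,
                 ps, pe)
  emit_bernoulli(agec >= 65, "high_risk_medication", care$high_risk_medication,
                 ps, pe)
  emit_bernoulli(agec >= 1 & agec <= 20, "fluoride_varnish",
                 care$fluoride_varnish, ps, pe)
  bmi <- which(agec >= 3 & agec <= 17 & stats::runif(n_pat) < care$bmi_percentile)
  emit(bmi, "bmi_percentile", runif_date_int(length(bmi), ps, pe),
       value = round(stats::runif(length(bmi), 1, 99), 1))

  # repeated observations with values
  dia <- which(has$diabetes)
  n_a1c <- stats::rpois(length(dia), cfg$event_rates$hba1c)
  a1c_p <- rep(dia, n_a1c)
  emit(a1c_p, "hba1c", runif_date_int(length(a1c_p), ps, pe),
       value = round(pmin(pmax(stats::rnorm(length(a1c_p), 8.2, 1.3), 4.5), 15), 1))
  hyp <- which(has$hypertension)
  n_bp <- 1L + stats::rpois(length(hyp), max(cfg$event_rates$bp_reading - 1, 0))
  bp_p <- rep(hyp, n_bp)
  emit(bp_p, "bp_reading", runif_date_int(length(bp_p), ps, pe),
       value = round(stats::rnorm(length(bp_p), 138, 16)),
       value2 = round(stats::rnorm(length(bp_p), 84, 11)))

  ev <- data.frame(
    pidx = unlist(acc$pidx, use.names = FALSE),
    concept = unlist(acc$concept, use.names = FALSE),
    date = unlist(acc$date, use.names = FALSE),
    value = unlist(acc$value, use.names = FALSE),
    value2 = unlist(acc$value2, use.names = FALSE),
    stringsAsFactors = FALSE
  )

  ## -- facility assignment -------------------------------------------------
  multi <- stats::runif(n_pat) < cfg$multi_facility_rate
  external <- multi[ev$pidx] & stats::runif(nrow(ev)) < cfg$theta
  fac_by_org <- split(facilities$facility_id, facilities$org_id)
  ev$facility_id <- NA_character_
  ev_org <- p_org[ev$pidx]
  for (o in org_id) {
    own <- fac_by_org[[o]]
    other <- setdiff(facilities$facility_id, own)
    i <- which(ev_org == o & !external)
    if (length(i)) ev$facility_id[i] <- own[sample.int(length(own), length(i),
                                                       replace = TRUE)]
    j <- which(ev_org == o & external)
    if (length(j)) ev$facility_id[j] <- other[sample.int(length(other), length(j),
                                                         replace = TRUE)]
  }

  # an encounter accompanies every clinical fact at its facility and date
  clin <- ev[ev$concept != "encounter", , drop = FALSE]
  if (nrow(clin) > 0) {
    key <- paste(clin$pidx, clin$facility_id, clin$date, sep = "\r")
    first <- clin[!duplicated(key), c("pidx", "concept", "date", "value",
                                      "value2", "facility_id"), drop = FALSE]
    first$concept <- "encounter"
    first$value <- NA_real_
    first$value2 <- NA_real_
    ev <- rbind(ev, first)
  }

  registry <- concept_registry()
  ev$event_type <- registry$event_type[match(ev$concept, registry$concept)]

  ## -- documents (bundle per facility and service date) --------------------
  ord <- order(ev$pidx, ev$facility_id, ev$date, ev$concept, ev$value,
               method = "radix", na.last = TRUE)
  ev <- ev[ord, , drop = FALSE]
  doc_key <- paste(ev$pidx, ev$facility_id, ev$date, sep = "\r")
  doc_of <- match(doc_key, unique(doc_key))
  n_doc <- max(doc_of)
  doc_first <- which(!duplicated(doc_key))
  documents <- data.frame(
    doc_id = sprintf("d%07d", seq_len(n_doc)),
    patient_id = patients$patient_id[ev$pidx[doc_first]],
    facility_id = ev$facility_id[doc_first],
    service_date = as.Date(ev$date[doc_first], origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  documents$received_at <- as.POSIXct(ev$date[doc_first] * 86400, tz = "UTC",
                                      origin = "1970-01-01") +
    round(stats::runif(n_doc, 3600, 172800))

  events <- data.frame(
    doc_id = documents$doc_id[doc_of],
    patient_id = patients$patient_id[ev$pidx],
    facility_id = ev$facility_id,
    event_type = ev$event_type,
    concept = ev$concept,
    value = ev$value,
    value2 = ev$value2,
    event_date = as.Date(ev$date, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  # duplicate documents: identical content, later receipt timestamp
  dup <- which(stats::runif(n_doc) < cfg$duplicate_rate)
  if (length(dup) > 0) {
    ddocs <- documents[dup, , drop = FALSE]
    ddocs$doc_id <- paste0(ddocs$doc_id, "x")
    ddocs$received_at <- ddocs$received_at +
      round(stats::runif(length(dup), 3600, 5 * 86400))
    devs <- events[events$doc_id %in% documents$doc_id[dup], , drop = FALSE]
    devs$doc_id <- paste0(devs$doc_id, "x")
    documents <- rbind(documents, ddocs)
    events <- rbind(events, devs)
  }
  ord_d <- order(documents$patient_id, documents$facility_id,
                 documents$service_date, documents$doc_id, method = "radix")
  documents <- documents[ord_d, , drop = FALSE]
  rownames(documents) <- NULL
  ord_e <- order(events$patient_id, events$facility_id, events$event_date,
                 events$doc_id, events$concept, method = "radix")
  events <- events[ord_e, , drop = FALSE]
  rownames(events) <- NULL

  fqm_population(patients, facilities, documents, events, config = cfg)
}
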