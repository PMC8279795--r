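# Shared fixtures, all built in code.

PERIOD <- measurement_period("2018-01-01", "2018-12-31")

REGISTRY <- concept_registry()
CATALOG <- measure_catalog()

# A minimal events data frame for one patient at one facility.
make_events <- function(concepts, dates, value = NA_real_, value2 = NA_real_,
                        patient_id = "p1", facility_id = "f1") {
  n <- length(concepts)
  data.frame(
    doc_id = sprintf("doc%03d", seq_len(n)),
    patient_id = rep_len(patient_id, n),
    facility_id = rep_len(facility_id, n),
    event_type = REGISTRY$event_type[match(concepts, REGISTRY$concept)],
    concept = concepts,
    value = rep_len(as.numeric(value), n),
    value2 = rep_len(as.numeric(value2), n),
    event_date = as.Date(dates),
    stringsAsFactors = FALSE
  )
}

make_patient <- function(birth = "1950-06-15", sex = "female",
                         patient_id = "p1", originating_org = "orgA") {
  list(patient_id = patient_id, sex = sex, birth_date = as.Date(birth),
       race = "white", ethnicity = "non_hispanic",
       originating_org = originating_org)
}

# Two-organization population with hand-placed documents, for the records
# and scope tests.
tiny_population <- function() {
  facilities <- data.frame(
    facility_id = c("a1", "a2", "b1"),
    org_id = c("orgA", "orgA", "orgB"),
    org_type = c("health_system", "health_system", "ambulatory_practice"),
    stringsAsFactors = FALSE
  )
  patients <- data.frame(
    patient_id = c("p1", "p2"),
    sex = c("female", "male"),
    birth_date = as.Date(c("1950-06-15", "2010-03-01")),
    race = "white", ethnicity = "non_hispanic",
    originating_org = c("orgA", "orgB"),
    stringsAsFactors = FALSE
  )
  documents <- data.frame(
    doc_id = sprintf("d%02d", 1:5),
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    facility_id = c("a1", "a2", "b1", "b1", "a1"),
    service_date = as.Date(c("2018-02-01", "2018-03-01", "2018-04-01",
                             "2018-05-01", "2018-06-01")),
    received_at = as.POSIXct("2018-12-01 10:00:00", tz = "UTC") + (1:5) * 60,
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    doc_id = documents$doc_id,
    patient_id = documents$patient_id,
    facility_id = documents$facility_id,
    event_type = "encounter",
    concept = "encounter",
    value = NA_real_, value2 = NA_real_,
    event_date = documents$service_date,
    stringsAsFactors = FALSE
  )
  fqm_population(patients, facilities, documents, events)
}

# Small generator configuration for fast end-to-end tests.
small_config <- function(...) {
  generator_config(n_health_systems = 2, n_ambulatory_practices = 3,
                   patients_per_org = 50, ...)
}

# Paired-results data frame builder: rep_counts is a named vector of
# "ORIGIN>ALL" -> count.
make_paired <- function(rep_counts, measure_id = "cms165") {
  pairs <- strsplit(names(rep_counts), ">", fixed = TRUE)
  origin <- rep(vapply(pairs, `[`, character(1), 1), rep_counts)
  all <- rep(vapply(pairs, `[`, character(1), 2), rep_counts)
  data.frame(
    patient_id = sprintf("p%05d", seq_along(origin)),
    measure_id = measure_id,
    origin_outcome = origin,
    all_outcome = all,
    stringsAsFactors = FALSE
  )
}

# External-record fraction of a deduplicated population.
external_fraction <- function(pop, unit = c("events", "documents")) {
  unit <- match.arg(unit)
  x <- pop[[unit]]
  org <- pop$facilities$org_id[match(x$facility_id, pop$facilities$facility_id)]
  porg <- pop$patients$originating_org[match(x$patient_id,
                                             pop$patients$patient_id)]
  mean(org != porg)
}
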