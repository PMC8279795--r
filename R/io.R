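# Population serialization: newline-delimited JSON for document records
# (one document with nested events per line) plus patients and facilities
# CSVs.

iso_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a population to a directory
#'
#' Produces \code{patients.csv}, \code{facilities.csv} and
#' \code{documents.ndjson} (one JSON document record per line, events
#' nested).
#'
#' @param population An \code{\link{fqm_population}}.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(population$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(population$facilities, file.path(dir, "facilities.csv"),
                   row.names = FALSE)
  docs <- population$documents
  ev <- population$events
  ev_cols <- c("event_type", "concept", "value", "value2", "event_date")
  ev_by_doc <- split(ev[ev_cols], factor(ev$doc_id, levels = docs$doc_id))
  con <- file(file.path(dir, "documents.ndjson"), open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    rec <- list(doc_id = docs$doc_id[i],
                patient_id = docs$patient_id[i],
                facility_id = docs$facility_id[i],
                service_date = format(docs$service_date[i]),
                received_at = iso_ts(docs$received_at[i]),
                events = ev_by_doc[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(dir)
}

#' Read a population from a directory
#'
#' Inverse of \code{\link{write_population}}.
#'
#' @param dir Directory containing \code{patients.csv},
#'   \code{facilities.csv} and \code{documents.ndjson}.
#' @return An \code{\link{fqm_population}}.
#' @export
read_population <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  patients$birth_date <- as.Date(patients$birth_date)
  facilities <- utils::read.csv(file.path(dir, "facilities.csv"),
                                stringsAsFactors = FALSE)
  lines <- readLines(file.path(dir, "documents.ndjson"))
  recs <- lapply(lines, jsonlite::fromJSON)
  docs <- data.frame(
    doc_id = vapply(recs, `[[`, character(1), "doc_id"),
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    facility_id = vapply(recs, `[[`, character(1), "facility_id"),
    service_date = as.Date(vapply(recs, `[[`, character(1), "service_date")),
    received_at = as.POSIXct(vapply(recs, `[[`, character(1), "received_at"),
                             format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  ev_list <- lapply(recs, function(r) {
    e <- as.data.frame(r$events, stringsAsFactors = FALSE)
    e$doc_id <- r$doc_id
    e$patient_id <- r$patient_id
    e$facility_id <- r$facility_id
    e
  })
  events <- do.call(rbind, ev_list)
  events$event_date <- as.Date(events$event_date)
  events$value <- as.numeric(events$value)
  events$value2 <- as.numeric(events$value2)
  events <- events[c("doc_id", "patient_id", "facility_id", "event_type",
                     "concept", "value", "value2", "event_date")]
  rownames(events) <- NULL
  fqm_population(patients, facilities, docs, events)
}

#' Ingest a serialized population
#'
#' Reads, validates and deduplicates a population directory, logging how
#' many duplicate documents were removed.
#'
#' @param dir Population directory (see \code{\link{write_population}}).
#' @param quiet Suppress log messages.
#' @return A deduplicated \code{\link{fqm_population}}.
#' @export
ingest_population <- function(dir, quiet = FALSE) {
  pop <- read_population(dir)
  n0 <- nrow(pop$documents)
  pop <- deduplicate_documents(pop)
  if (!quiet) {
    message(sprintf("ingest: %d documents read, %d duplicates removed, %d retained",
                    n0, n0 - nrow(pop$documents), nrow(pop$documents)))
  }
  pop
}
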