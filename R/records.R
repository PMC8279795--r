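# Clinical data model: document deduplication, facility activity filtering,
# patient sampling, and scope resolution (originating organization vs all
# sources).
#
# Containers are plain data frames:
#   facilities: facility_id, org_id, org_type ("health_system" or
#               "ambulatory_practice")
#   patients:   patient_id, sex ("female"/"male"), birth_date (Date), race,
#               ethnicity, originating_org
#   documents:  doc_id, patient_id, facility_id, service_date (Date),
#               received_at (POSIXct)
#   events:     doc_id, patient_id, facility_id, event_type, concept,
#               value, value2 (numeric, NA unless the concept carries one),
#               event_date (Date)

ORG_TYPES <- c("health_system", "ambulatory_practice")

#' Assemble a population object
#'
#' Bundles the four record tables into a single \code{fqm_population}. Basic
#' referential integrity is checked: every document's patient and facility
#' must exist, and events must belong to a document.
#'
#' @param patients,facilities,documents,events Data frames with the columns
#'   described in the package overview (see \code{\link{generate_population}}).
#' @param config Optional generator configuration to attach.
#' @return An object of class \code{fqm_population}.
#' @export
fqm_population <- function(patients, facilities, documents, events,
                           config = NULL) {
  if (!all(documents$patient_id %in% patients$patient_id)) {
    stop("document references unknown patient_id")
  }
  if (!all(documents$facility_id %in% facilities$facility_id)) {
    stop("document references unknown facility_id")
  }
  if (!all(events$doc_id %in% documents$doc_id)) {
    stop("event references unknown doc_id")
  }
  if (!all(patients$originating_org %in% facilities$org_id)) {
    stop("patient originating_org not present among facilities")
  }
  structure(
    list(patients = patients, facilities = facilities,
         documents = documents, events = events, config = config),
    class = "fqm_population"
  )
}

#' @export
print.fqm_population <- function(x, ...) {
  cat("Synthetic clinical population\n")
  cat(sprintf("  organizations: %d (%d facilities)\n",
              length(unique(x$facilities$org_id)), nrow(x$facilities)))
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  documents:     %d\n", nrow(x$documents)))
  cat(sprintf("  events:        %d\n", nrow(x$events)))
  invisible(x)
}

# Stable per-document content key used only to break receipt-time ties:
# the sorted concatenation of each document's event fields.
document_content_key <- function(documents, events) {
  ev_key <- paste(events$event_type, events$concept,
                  format(events$event_date),
                  events$value, events$value2, sep = ";")
  keys <- vapply(split(ev_key, factor(events$doc_id, levels = documents$doc_id)),
                 function(k) paste(sort(k), collapse = "|"), character(1))
  unname(keys)
}

#' Remove duplicate document records
#'
#' For each (patient, facility, service date) group only the most recently
#' received document is retained; documents are never merged across dates or
#' facilities. Receipt-time ties are broken by a stable content key so the
#' result is deterministic. Output is sorted by patient, facility and date.
#'
#' @param x An \code{fqm_population}, or a documents data frame.
#' @param events Events data frame (only used when \code{x} is a data frame,
#'   to build content keys for tie-breaking; optional).
#' @return Same shape as the input: a deduplicated population (events of
#'   dropped documents are dropped too) or a deduplicated documents frame.
#' @export
deduplicate_documents <- function(x, events = NULL) {
  if (inherits(x, "fqm_population")) {
    docs <- dedup_docs_df(x$documents, x$events)
    keep <- x$events$doc_id %in% docs$doc_id
    out <- x
    out$documents <- docs
    out$events <- x$events[keep, , drop = FALSE]
    rownames(out$events) <- NULL
    return(out)
  }
  dedup_docs_df(x, events)
}

dedup_docs_df <- function(documents, events = NULL) {
  if (nrow(documents) == 0) return(documents)
  if (anyNA(documents$received_at)) {
    stop("received_at must be populated on all documents")
  }
  key <- paste(documents$patient_id, documents$facility_id,
               format(documents$service_date), sep = "\r")
  tiebreak <- if (!is.null(events)) {
    document_content_key(documents, events)
  } else {
    documents$doc_id
  }
  ord <- order(documents$patient_id, documents$facility_id,
               documents$service_date,
               -as.numeric(documents$received_at),
               tiebreak, method = "radix")
  docs <- documents[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- docs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter facilities by sustained document activity
#'
#' A facility qualifies when it exceeded the monthly document threshold in
#' strictly more than \code{min_months} of the 12 months (the "more than 6
#' months" rule read literally, i.e. at least 7 qualifying months by
#' default).
#'
#' @param monthly_counts A matrix or data frame with one row per facility
#'   (rownames = facility ids) and exactly 12 monthly document counts, or a
#'   named list of length-12 count vectors.
#' @param min_docs Monthly document threshold (inclusive; default 100).
#' @param min_months Number of qualifying months that must be exceeded
#'   (default 6).
#' @return Character vector of qualifying facility ids.
#' @export
facility_activity_filter <- function(monthly_counts, min_docs = 100,
                                     min_months = 6) {
  if (is.list(monthly_counts) && !is.data.frame(monthly_counts)) {
    bad <- lengths(monthly_counts) != 12L
    if (any(bad)) stop("each facility needs exactly 12 monthly counts")
    monthly_counts <- do.call(rbind, monthly_counts)
  }
  monthly_counts <- as.matrix(monthly_counts)
  if (ncol(monthly_counts) != 12L) {
    stop("each facility needs exactly 12 monthly counts")
  }
  if (is.null(rownames(monthly_counts))) {
    rownames(monthly_counts) <- as.character(seq_len(nrow(monthly_counts)))
  }
  qualifying <- rowSums(monthly_counts >= min_docs)
  rownames(monthly_counts)[qualifying > min_months]
}

#' Sample patients from an organization
#'
#' Uniform sampling without replacement, deterministic for a given seed. If
#' fewer than \code{n} candidates exist, all are returned with a warning.
#'
#' @param org_patients Character vector of candidate patient ids.
#' @param n Number of patients to draw.
#' @param seed Integer seed.
#' @return Character vector of sampled ids.
#' @export
sample_patients <- function(org_patients, n, seed) {
  stopifnot_count(n, "n")
  if (length(org_patients) == 0) stop("no candidate patients to sample from")
  if (length(org_patients) < n) {
    warning(sprintf("only %d candidates available; returning all (requested %d)",
                    length(org_patients), n))
    return(org_patients)
  }
  with_seed(seed, sample(org_patients, n))
}

#' Resolve the events visible under a calculation scope
#'
#' \code{origin_only} keeps events recorded at facilities belonging to the
#' patient's originating organization (the single-EHR view);
#' \code{all_sources} keeps every event. The origin-only result is always a
#' subset of the all-sources result.
#'
#' @param patient One-row data frame (or list) with \code{patient_id} and
#'   \code{originating_org}.
#' @param events Events data frame, already deduplicated.
#' @param facilities Facilities data frame mapping facility ids to
#'   organizations.
#' @param scope \code{"origin_only"} or \code{"all_sources"}.
#' @return The filtered events data frame.
#' @export
scope_events <- function(patient, events, facilities,
                         scope = c("origin_only", "all_sources")) {
  scope <- match.arg(scope)
  ev <- events[events$patient_id == patient$patient_id, , drop = FALSE]
  unknown <- setdiff(unique(ev$facility_id), facilities$facility_id)
  if (length(unknown) > 0) {
    stop(sprintf("unknown facility id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (scope == "all_sources") return(ev)
  org <- facilities$org_id[match(ev$facility_id, facilities$facility_id)]
  out <- ev[org == patient$originating_org, , drop = FALSE]
  rownames(out) <- NULL
  out
}
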