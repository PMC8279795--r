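# The measure engine: evaluates one simplified eCQM emulation for one
# patient to one of four outcomes. Outcome precedence is strict:
# denominator eligibility, then exclusion, then numerator. All denominator
# logic is existential (presence of events), so adding events can never make
# an eligible patient not applicable.

OUTCOMES <- c("NOT_APPLICABLE", "EXCLUDED", "NONCOMPLIANT", "COMPLIANT")

#' The four measure outcome states, in canonical order
#' @return Character vector of the four outcome labels.
#' @export
outcome_levels <- function() OUTCOMES

# Column-vector view of a patient's events for fast repeated scans.
compile_events <- function(events) {
  list(concept = events$concept,
       date = as.integer(as.Date(events$event_date)),
       value = events$value,
       value2 = events$value2)
}

any_concept_in <- function(ce, concepts, lo, hi) {
  any(ce$concept %in% concepts & ce$date >= lo & ce$date <= hi)
}

#' Denominator (eligibility) resolution
#'
#' A patient is eligible when the sex restriction matches, completed age at
#' the period-end anchor falls in the measure's range, every required
#' condition has at least one event inside its window, and (when required) a
#' qualifying encounter falls inside the measurement period. Eligibility
#' depends only on the presence of events, never their absence.
#'
#' @param defn A measure definition from \code{\link{measure_catalog}}.
#' @param patient List or one-row data frame with \code{sex} and
#'   \code{birth_date}.
#' @param events The patient's events data frame (one calculation scope).
#' @param period A \code{\link{measurement_period}}.
#' @return Logical flag.
#' @export
resolve_denominator <- function(defn, patient, events, period) {
  resolve_denominator_ce(defn, patient, compile_events(events), period)
}

resolve_denominator_ce <- function(defn, patient, ce, period) {
  if (!is.na(defn$sex) && patient$sex != defn$sex) return(FALSE)
  age <- age_on(patient$birth_date, period$end)
  if (age < defn$age$min || age > defn$age$max) return(FALSE)
  if (defn$episodic) {
    return(length(find_episodes(defn, ce, period)$dx) > 0)
  }
  for (cond in defn$conditions) {
    b <- window_bounds(cond$window, period)
    if (!any_concept_in(ce, cond$concept, b[1], b[2])) return(FALSE)
  }
  if (defn$requires_encounter &&
      !any_concept_in(ce, "encounter",
                      as.integer(period$start), as.integer(period$end))) {
    return(FALSE)
  }
  TRUE
}

#' Exclusion resolution
#'
#' Assumes denominator eligibility; a patient is excluded when any exclusion
#' concept has an event inside its window (e.g. ever on/before the period
#' end for prior surgeries, during the period for pregnancy or hospice).
#'
#' @inheritParams resolve_denominator
#' @return Logical flag.
#' @export
resolve_exclusion <- function(defn, patient, events, period) {
  resolve_exclusion_ce(defn, compile_events(events), period)
}

resolve_exclusion_ce <- function(defn, ce, period) {
  for (ex in defn$exclusions) {
    b <- window_bounds(ex$window, period)
    if (any_concept_in(ce, ex$concepts, b[1], b[2])) return(TRUE)
  }
  FALSE
}

#' Raw numerator resolution
#'
#' The raw numerator is met when any numerator rule is satisfied: a
#' qualifying event inside the rule's lookback window, with the rule's value
#' predicate (if any) applied to the most recent qualifying observation.
#' Same-date observation ties are broken by a stable ordering (concept, then
#' values). For the raw-met interpretation of inverse measures see
#' \code{\link{evaluate_measure}}.
#'
#' @inheritParams resolve_denominator
#' @return Logical flag (\code{raw_met}).
#' @export
resolve_numerator <- function(defn, patient, events, period) {
  resolve_numerator_ce(defn, patient, compile_events(events), period)
}

resolve_numerator_ce <- function(defn, patient, ce, period) {
  age <- age_on(patient$birth_date, period$end)
  for (rule in defn$numerator) {
    if (!is.null(rule$min_age) && age < rule$min_age) next
    b <- window_bounds(rule$window, period)
    idx <- which(ce$concept %in% rule$concepts &
                   ce$date >= b[1] & ce$date <= b[2])
    if (is.null(rule$predicate)) {
      if (length(idx) > 0) return(TRUE)
    } else if (length(idx) == 0) {
      if (identical(rule$predicate$missing, "met")) return(TRUE)
    } else {
      latest <- idx[ce$date[idx] == max(ce$date[idx])]
      if (length(latest) > 1) {
        ord <- order(ce$concept[latest], ce$value[latest], ce$value2[latest],
                     method = "radix", na.last = TRUE)
        latest <- latest[ord[length(ord)]]
      }
      if (apply_predicate(rule$predicate, ce$value[latest], ce$value2[latest])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

apply_predicate <- function(pred, value, value2) {
  res <- switch(pred$op,
    gt = value > pred$threshold,
    bp_lt = value < pred$systolic & value2 < pred$diastolic,
    stop(sprintf("unknown predicate op '%s'", pred$op))
  )
  isTRUE(res)
}

# Pharyngitis episodes: a pharyngitis diagnosis during the period with an
# antibiotic dispensed within `antibiotic_within_days` after it. Returns the
# distinct episode dates with per-episode exclusion (antibiotic in the prior
# `prior_antibiotic_days`) and testing flags.
find_episodes <- function(defn, ce, period) {
  ep <- defn$episode
  dx <- sort(unique(ce$date[ce$concept == ep$dx_concept &
                              ce$date >= as.integer(period$start) &
                              ce$date <= as.integer(period$end)]))
  if (length(dx) == 0) {
    return(list(dx = integer(0), excluded = logical(0), tested = logical(0)))
  }
  abx <- ce$date[ce$concept %in% ep$antibiotic_concepts]
  tst <- ce$date[ce$concept %in% ep$test_concepts]
  has_abx <- vapply(dx, function(d)
    any(abx >= d & abx <= d + ep$antibiotic_within_days), logical(1))
  dx <- dx[has_abx]
  excluded <- vapply(dx, function(d)
    any(abx >= d - ep$prior_antibiotic_days & abx <= d - 1), logical(1))
  tested <- vapply(dx, function(d)
    any(tst >= d - ep$test_within_days & tst <= d + ep$test_within_days),
    logical(1))
  list(dx = dx, excluded = excluded, tested = tested)
}

#' Evaluate one measure for one patient
#'
#' Applies the strict precedence: \code{NOT_APPLICABLE} if the denominator
#' is not met, else \code{EXCLUDED} if any exclusion applies, else the raw
#' numerator maps to \code{COMPLIANT}/\code{NONCOMPLIANT} -- with the
#' mapping inverted for inverse measures, where the raw numerator (poor
#' glycemic control, a high-risk medication order) is the undesirable event.
#' For the episodic pharyngitis measure the patient is eligible when at
#' least one qualifying episode exists and compliant when every
#' non-excluded episode was tested.
#'
#' @inheritParams resolve_denominator
#' @return One of \code{outcome_levels()}.
#' @export
evaluate_measure <- function(defn, patient, events, period) {
  evaluate_measure_ce(defn, patient, compile_events(events), period)
}

evaluate_measure_ce <- function(defn, patient, ce, period) {
  if (defn$episodic) return(evaluate_episodic_ce(defn, patient, ce, period))
  if (!resolve_denominator_ce(defn, patient, ce, period)) {
    return("NOT_APPLICABLE")
  }
  if (resolve_exclusion_ce(defn, ce, period)) return("EXCLUDED")
  raw <- resolve_numerator_ce(defn, patient, ce, period)
  if (xor(raw, defn$inverse)) "COMPLIANT" else "NONCOMPLIANT"
}

evaluate_episodic_ce <- function(defn, patient, ce, period) {
  if (!is.na(defn$sex) && patient$sex != defn$sex) return("NOT_APPLICABLE")
  age <- age_on(patient$birth_date, period$end)
  if (age < defn$age$min || age > defn$age$max) return("NOT_APPLICABLE")
  eps <- find_episodes(defn, ce, period)
  if (length(eps$dx) == 0) return("NOT_APPLICABLE")
  keep <- !eps$excluded
  if (!any(keep)) return("EXCLUDED")
  if (all(eps$tested[keep])) "COMPLIANT" else "NONCOMPLIANT"
}

#' Evaluate the full catalog for one patient
#'
#' @param catalog A \code{\link{measure_catalog}}.
#' @inheritParams resolve_denominator
#' @return Named character vector (one outcome per measure).
#' @export
evaluate_patient <- function(catalog, patient, events, period) {
  ce <- compile_events(events)
  vapply(catalog, evaluate_measure_ce, character(1),
         patient = patient, ce = ce, period = period)
}
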