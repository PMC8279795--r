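# Dual-scope evaluation, discrepancy classification and aggregation.
#
# Every patient x measure pair is evaluated twice: once on events from the
# originating organization only, once on all sources. The all-sources scope
# is the reference standard, so "applicable" means applicable under all
# sources; becoming newly applicable (NA -> NC / NA -> CC) therefore counts
# among applicable calculations.

CATEGORIES <- c("NONE", "NA_TO_NC", "NA_TO_CC", "NC_TO_CC", "CC_TO_NC", "OTHER")

#' Discrepancy category labels, in canonical order
#' @return Character vector of the six category labels.
#' @export
category_levels <- function() CATEGORIES

#' Paired dual-scope measure evaluation
#'
#' Evaluates every measure in the catalog for every patient under both
#' calculation scopes. Documents must be deduplicated first (see
#' \code{\link{deduplicate_documents}}).
#'
#' @param population A deduplicated \code{\link{fqm_population}}.
#' @param catalog A \code{\link{measure_catalog}}.
#' @param period A \code{\link{measurement_period}}.
#' @return Data frame with one row per patient x measure:
#'   \code{patient_id}, \code{measure_id}, \code{origin_outcome},
#'   \code{all_outcome}.
#' @export
paired_evaluate <- function(population, catalog = measure_catalog(),
                            period = measurement_period()) {
  pats <- population$patients
  ev <- population$events
  fac <- population$facilities
  ev_org <- fac$org_id[match(ev$facility_id, fac$facility_id)]
  if (anyNA(ev_org)) stop("events reference unknown facility ids")

  date_int <- as.integer(as.Date(ev$event_date))
  pat_f <- factor(ev$patient_id, levels = pats$patient_id)
  idx_by_pat <- split(seq_len(nrow(ev)), pat_f)
  origin_of <- pats$originating_org

  n_m <- length(catalog)
  out_origin <- out_all <- matrix(NA_character_, nrow(pats), n_m)
  for (i in seq_len(nrow(pats))) {
    patient <- list(sex = pats$sex[i], birth_date = pats$birth_date[i])
    rows <- idx_by_pat[[i]]
    ce_all <- list(concept = ev$concept[rows], date = date_int[rows],
                   value = ev$value[rows], value2 = ev$value2[rows])
    own <- ev_org[rows] == origin_of[i]
    ce_org <- list(concept = ce_all$concept[own], date = ce_all$date[own],
                   value = ce_all$value[own], value2 = ce_all$value2[own])
    for (m in seq_len(n_m)) {
      out_all[i, m] <- evaluate_measure_ce(catalog[[m]], patient, ce_all, period)
      out_origin[i, m] <- evaluate_measure_ce(catalog[[m]], patient, ce_org,
                                              period)
    }
  }
  data.frame(
    patient_id = rep(pats$patient_id, each = n_m),
    measure_id = rep(names(catalog), nrow(pats)),
    origin_outcome = as.vector(t(out_origin)),
    all_outcome = as.vector(t(out_all)),
    stringsAsFactors = FALSE
  )
}

#' Classify a paired outcome transition
#'
#' Equal outcomes map to \code{NONE}; the four named transitions follow the
#' discrepancy taxonomy (newly applicable to noncompliant/compliant,
#' noncompliant to compliant, compliant to noncompliant); every other
#' unequal pair -- any involving \code{EXCLUDED}, or newly applicable to
#' excluded -- is pooled into \code{OTHER}.
#'
#' @param origin,all Character vectors of outcomes (recycled to a common
#'   length).
#' @return Character vector of \code{category_levels()}.
#' @export
classify_transition <- function(origin, all) {
  n <- max(length(origin), length(all))
  origin <- rep_len(as.character(origin), n)
  all <- rep_len(as.character(all), n)
  bad <- !(origin %in% OUTCOMES) | !(all %in% OUTCOMES)
  if (any(bad)) stop("unknown outcome label")
  out <- rep("OTHER", n)
  out[origin == all] <- "NONE"
  out[origin == "NOT_APPLICABLE" & all == "NONCOMPLIANT"] <- "NA_TO_NC"
  out[origin == "NOT_APPLICABLE" & all == "COMPLIANT"] <- "NA_TO_CC"
  out[origin == "NONCOMPLIANT" & all == "COMPLIANT"] <- "NC_TO_CC"
  out[origin == "COMPLIANT" & all == "NONCOMPLIANT"] <- "CC_TO_NC"
  out
}

#' Paired transition table
#'
#' The 4 x 4 contingency table of origin-scope by all-sources outcomes.
#'
#' @param origin,all Character vectors of outcomes.
#' @return Integer matrix with \code{outcome_levels()} dimnames.
#' @export
transition_table <- function(origin, all) {
  table(factor(origin, levels = OUTCOMES), factor(all, levels = OUTCOMES))
}

#' Performance rate
#'
#' Compliant over compliant-plus-noncompliant; excluded and not-applicable
#' outcomes never enter the denominator. Undefined (no compliant or
#' noncompliant outcome at all) is reported as \code{NA}, never as zero.
#'
#' @param outcomes Character vector of outcomes.
#' @return Rate in [0, 1], or \code{NA_real_} when undefined.
#' @export
performance_rate <- function(outcomes) {
  cc <- sum(outcomes == "COMPLIANT")
  nc <- sum(outcomes == "NONCOMPLIANT")
  if (cc + nc == 0) return(NA_real_)
  cc / (cc + nc)
}

#' Net compliance change for one measure
#'
#' 100 x (all-sources performance rate - origin performance rate), in
#' percentage points. The origin rate is computed over origin-applicable
#' outcomes only (what single-EHR reporting would submit); the all-sources
#' rate over all-sources-applicable outcomes.
#'
#' @param paired Paired-results data frame from \code{\link{paired_evaluate}}.
#' @param measure_id Measure to summarize.
#' @return Percentage points, or \code{NA} (with a warning naming the
#'   undefined side) when either rate has an empty denominator.
#' @export
compliance_change <- function(paired, measure_id) {
  rows <- paired[paired$measure_id == measure_id, , drop = FALSE]
  if (nrow(rows) == 0) stop(sprintf("no paired results for %s", measure_id))
  r_origin <- performance_rate(rows$origin_outcome)
  r_all <- performance_rate(rows$all_outcome)
  if (is.na(r_origin) || is.na(r_all)) {
    side <- c("origin-scope", "all-sources")[c(is.na(r_origin), is.na(r_all))]
    warning(sprintf("compliance change for %s not computable: %s rate undefined",
                    measure_id, paste(side, collapse = " and ")))
    return(NA_real_)
  }
  100 * (r_all - r_origin)
}

#' Aggregate paired results into a report
#'
#' Builds the per-measure summaries (applicable counts, discrepancy
#' category counts, performance rates, net compliance change, Monte Carlo
#' symmetry test with FDR-adjusted q-values), the pooled overall symmetry
#' test, per-organization discrepancy rates, and per-patient any-change
#' flags. "Applicable" means applicable under the all-sources reference
#' scope.
#'
#' @param paired Paired-results data frame from \code{\link{paired_evaluate}}.
#' @param population The population the results came from (for organization
#'   lookup).
#' @param n_resamples Monte Carlo resamples per measure test.
#' @param seed Seed for the Monte Carlo tests.
#' @return An object of class \code{fqm_report}.
#' @export
aggregate_report <- function(paired, population, n_resamples = 2000,
                             seed = 1L) {
  paired$category <- classify_transition(paired$origin_outcome,
                                         paired$all_outcome)
  applicable <- paired$all_outcome != "NOT_APPLICABLE"
  measures <- unique(paired$measure_id)

  per_measure <- lapply(measures, function(mid) {
    rows <- paired[paired$measure_id == mid, , drop = FALSE]
    app <- rows[rows$all_outcome != "NOT_APPLICABLE", , drop = FALSE]
    cats <- table(factor(app$category, levels = CATEGORIES))
    tab <- transition_table(rows$origin_outcome, rows$all_outcome)
    mc <- monte_carlo_symmetry_test(tab, n_resamples = n_resamples,
                                    seed = seed)
    r_origin <- performance_rate(rows$origin_outcome)
    r_all <- performance_rate(rows$all_outcome)
    list(measure_id = mid,
         applicable = nrow(app),
         discrepancies = sum(app$category != "NONE"),
         categories = as.integer(cats)[-1],  # drop NONE
         origin_rate = r_origin,
         all_rate = r_all,
         compliance_change = if (is.na(r_origin) || is.na(r_all)) NA_real_
                             else 100 * (r_all - r_origin),
         statistic = mc$statistic, dof = mc$dof, p_value = mc$p_value)
  })
  names(per_measure) <- measures
  p <- vapply(per_measure, `[[`, numeric(1), "p_value")
  q <- bh_fdr(p)
  for (i in seq_along(per_measure)) per_measure[[i]]$q_value <- q[i]

  overall_tab <- transition_table(paired$origin_outcome, paired$all_outcome)
  overall_asy <- symmetry_test(overall_tab)
  overall_mc <- monte_carlo_symmetry_test(overall_tab,
                                          n_resamples = n_resamples,
                                          seed = seed)

  # per-organization discrepancy rates over each organization's patients
  org_of <- population$patients$originating_org[
    match(paired$patient_id, population$patients$patient_id)]
  app_rows <- which(applicable)
  org_rates <- tapply(paired$category[app_rows] != "NONE", org_of[app_rows],
                      mean)
  org_rates_df <- data.frame(
    org_id = names(org_rates),
    org_type = population$facilities$org_type[
      match(names(org_rates), population$facilities$org_id)],
    applicable = as.integer(table(org_of[app_rows])[names(org_rates)]),
    discrepancy_rate = as.numeric(org_rates),
    stringsAsFactors = FALSE
  )
  rownames(org_rates_df) <- NULL

  # per-patient any-change flags, among patients with >= 1 applicable result
  pat_app <- tapply(applicable, paired$patient_id, any)
  pat_chg <- tapply(applicable & paired$category != "NONE", paired$patient_id,
                    any)
  patients_with_applicable <- sum(pat_app)
  patients_changed <- sum(pat_chg)

  structure(
    list(paired = paired,
         per_measure = per_measure,
         overall = list(
           applicable = sum(applicable),
           discrepancies = sum(applicable & paired$category != "NONE"),
           change_fraction = if (sum(applicable) == 0) 0
                             else mean(paired$category[applicable] != "NONE"),
           transition_table = overall_tab,
           statistic = overall_asy$statistic, dof = overall_asy$dof,
           p_asymptotic = overall_asy$p_value, p_monte_carlo = overall_mc$p_value),
         organizations = org_rates_df,
         patients = list(
           n = length(pat_app),
           with_applicable = patients_with_applicable,
           changed = patients_changed,
           changed_fraction = if (patients_with_applicable == 0) 0
                              else patients_changed / patients_with_applicable),
         n_resamples = n_resamples, seed = seed),
    class = "fqm_report"
  )
}

#' @export
print.fqm_report <- function(x, ...) {
  cat("Dual-scope quality measurement report\n")
  cat(sprintf("  applicable calculations: %d\n", x$overall$applicable))
  cat(sprintf("  discrepancies:           %d (%.1f%%)\n",
              x$overall$discrepancies, 100 * x$overall$change_fraction))
  cat(sprintf("  patients with a change:  %d of %d with applicable measures (%.1f%%)\n",
              x$patients$changed, x$patients$with_applicable,
              100 * x$patients$changed_fraction))
  cat(sprintf("  overall symmetry test:   chi^2 = %.2f, df = %d, p = %.3g (asymptotic)\n",
              x$overall$statistic, x$overall$dof, x$overall$p_asymptotic))
  cat("\n")
  print(render_table2(x))
  invisible(x)
}

#' @export
summary.fqm_report <- function(object, ...) {
  sig <- sum(vapply(object$per_measure, `[[`, numeric(1), "q_value") < 0.05)
  cat(sprintf("%d measures, %d with q < 0.05; %d/%d applicable calculations changed (%.1f%%)\n",
              length(object$per_measure), sig, object$overall$discrepancies,
              object$overall$applicable, 100 * object$overall$change_fraction))
  invisible(object)
}
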