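# End-to-end pipeline: simulate -> deduplicate -> paired evaluation ->
# statistics -> rendered report, fully deterministic given the
# configuration seed, with every intermediate artifact persistable.

#' Run the full fragmentation-impact pipeline
#'
#' Executes every stage in order with count logging: population generation,
#' document deduplication, dual-scope measure evaluation, discrepancy
#' classification, per-measure Monte Carlo symmetry tests with FDR
#' adjustment, and report rendering. When \code{out_dir} is given all
#' intermediate artifacts are written (population NDJSON + CSVs, paired
#' results CSV, report JSON, rendered summary table as CSV and text).
#'
#' @param config An \code{\link{generator_config}} (the study-emulation
#'   defaults if omitted).
#' @param catalog A \code{\link{measure_catalog}}.
#' @param n_resamples Monte Carlo resamples for the per-measure tests.
#' @param out_dir Optional artifact directory.
#' @param quiet Suppress stage logging.
#' @return An object of class \code{fqm_run}: list with \code{population}
#'   (deduplicated), \code{paired}, \code{report}, \code{table} and
#'   \code{config}.
#' @export
run_pipeline <- function(config = emulate_study_defaults(),
                         catalog = measure_catalog(),
                         n_resamples = 2000,
                         out_dir = NULL, quiet = FALSE) {
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  period <- config$period

  log("simulate: generating population (seed %d)", config$seed)
  pop <- generate_population(config)
  log("simulate: %d patients, %d facilities, %d documents, %d events",
      nrow(pop$patients), nrow(pop$facilities), nrow(pop$documents),
      nrow(pop$events))
  if (!is.null(out_dir)) {
    write_population(pop, file.path(out_dir, "population"))
  }

  n0 <- nrow(pop$documents)
  pop_d <- deduplicate_documents(pop)
  log("ingest: %d duplicate documents removed, %d retained",
      n0 - nrow(pop_d$documents), nrow(pop_d$documents))

  log("compare: evaluating %d measures x %d patients under both scopes",
      length(catalog), nrow(pop_d$patients))
  paired <- paired_evaluate(pop_d, catalog, period)

  report <- aggregate_report(paired, pop_d, n_resamples = n_resamples,
                             seed = config$seed)
  log("compare: %d applicable calculations, %d discrepancies (%.1f%%)",
      report$overall$applicable, report$overall$discrepancies,
      100 * report$overall$change_fraction)
  tab <- render_table2(report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$paired,
                     file.path(out_dir, "paired_results.csv"),
                     row.names = FALSE)
    write_report_json(report, file.path(out_dir, "report.json"))
    utils::write.csv(tab, file.path(out_dir, "measure_summary.csv"),
                     row.names = FALSE)
    writeLines(format_table2(tab), file.path(out_dir, "measure_summary.txt"))
    log("report: artifacts written to %s", out_dir)
  }

  structure(list(population = pop_d, paired = report$paired, report = report,
                 table = tab, config = config),
            class = "fqm_run")
}

#' @export
print.fqm_run <- function(x, ...) {
  cat(sprintf("Pipeline run: theta = %.3f, seed = %d\n\n",
              x$config$theta, x$config$seed))
  print(x$report)
  invisible(x)
}

#' Render the per-measure summary table
#'
#' One row per measure -- net compliance change (percentage points),
#' applicable calculations, the five discrepancy category counts, and the
#' FDR-adjusted q-value -- plus a totals row whose category counts equal
#' the column sums. Measures are ordered by compliance change. A measure
#' with no applicable calculations keeps \code{NA} (rendered as a dash in
#' the text form) rather than a zero rate.
#'
#' @param report An \code{fqm_report} from \code{\link{aggregate_report}}.
#' @return Data frame of class \code{fqm_table2}.
#' @export
render_table2 <- function(report) {
  pm <- report$per_measure
  df <- data.frame(
    measure_id = vapply(pm, `[[`, character(1), "measure_id"),
    compliance_change = vapply(pm, `[[`, numeric(1), "compliance_change"),
    applicable = vapply(pm, `[[`, numeric(1), "applicable"),
    stringsAsFactors = FALSE
  )
  cats <- t(vapply(pm, `[[`, numeric(5), "categories"))
  colnames(cats) <- c("na_to_nc", "na_to_cc", "nc_to_cc", "cc_to_nc", "other")
  df <- cbind(df, as.data.frame(cats))
  df$q_value <- vapply(pm, `[[`, numeric(1), "q_value")
  df <- df[order(df$compliance_change, df$measure_id, na.last = TRUE), ,
           drop = FALSE]
  total <- data.frame(measure_id = "total",
                      compliance_change = NA_real_,
                      applicable = sum(df$applicable),
                      na_to_nc = sum(df$na_to_nc),
                      na_to_cc = sum(df$na_to_cc),
                      nc_to_cc = sum(df$nc_to_cc),
                      cc_to_nc = sum(df$cc_to_nc),
                      other = sum(df$other),
                      q_value = NA_real_,
                      stringsAsFactors = FALSE)
  out <- rbind(df, total)
  rownames(out) <- NULL
  class(out) <- c("fqm_table2", "data.frame")
  out
}

format_table2 <- function(tab) {
  fmt <- function(x, digits) ifelse(is.na(x), "-", formatC(x, digits = digits,
                                                           format = "f"))
  lines <- sprintf("%-8s %9s %11s %9s %9s %9s %9s %7s %8s",
                   tab$measure_id, fmt(tab$compliance_change, 1),
                   tab$applicable, tab$na_to_nc, tab$na_to_cc, tab$nc_to_cc,
                   tab$cc_to_nc, tab$other, fmt(tab$q_value, 4))
  header <- sprintf("%-8s %9s %11s %9s %9s %9s %9s %7s %8s",
                    "measure", "change", "applicable", "NA->NC", "NA->CC",
                    "NC->CC", "CC->NC", "other", "q")
  c(header, lines)
}

#' @export
print.fqm_table2 <- function(x, ...) {
  writeLines(format_table2(x))
  invisible(x)
}

write_report_json <- function(report, path) {
  pm <- lapply(report$per_measure, function(m) {
    m$categories <- as.list(stats::setNames(m$categories,
                                            c("na_to_nc", "na_to_cc",
                                              "nc_to_cc", "cc_to_nc",
                                              "other")))
    m
  })
  obj <- list(
    overall = list(applicable = report$overall$applicable,
                   discrepancies = report$overall$discrepancies,
                   change_fraction = report$overall$change_fraction,
                   statistic = report$overall$statistic,
                   dof = report$overall$dof,
                   p_asymptotic = report$overall$p_asymptotic,
                   p_monte_carlo = report$overall$p_monte_carlo,
                   transition_table = unclass(unname(as.matrix(
                     report$overall$transition_table)))),
    per_measure = pm,
    organizations = report$organizations,
    patients = report$patients,
    n_resamples = report$n_resamples,
    seed = report$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
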