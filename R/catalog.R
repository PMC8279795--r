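# Declarative measure catalog and concept registry.

#' Concept registry
#'
#' The controlled concept labels used by the generator and the measure
#' engine, with event types, a value flag, and illustrative (not official)
#' terminology codes for ingest testing.
#'
#' @param path Optional path to a registry CSV; defaults to the registry
#'   shipped with the package.
#' @return Data frame with columns \code{concept}, \code{event_type},
#'   \code{has_value}, \code{example_code_system}, \code{example_code},
#'   \code{description}.
#' @export
concept_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "concept_registry.csv",
                                package = "fragqm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the measure catalog
#'
#' Reads the declarative YAML catalog of simplified eCQM emulations, checks
#' every referenced concept against the concept registry, and returns a
#' validated list of measure definitions.
#'
#' @param path Optional path to a catalog YAML; defaults to the catalog
#'   shipped with the package.
#' @param registry Concept registry data frame (defaults to
#'   \code{\link{concept_registry}()}).
#' @return An object of class \code{fqm_catalog}: a named list of measure
#'   definitions (class \code{fqm_measure}).
#' @export
measure_catalog <- function(path = NULL, registry = concept_registry()) {
  path <- path %||% system.file("extdata", "measure_catalog.yaml",
                                package = "fragqm", mustWork = TRUE)
  raw <- yaml::read_yaml(path)$measures
  defs <- lapply(raw, as_fqm_measure, registry = registry)
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  structure(defs, class = "fqm_catalog")
}

as_fqm_measure <- function(m, registry) {
  m$inverse <- isTRUE(m$inverse)
  m$episodic <- isTRUE(m$episodic)
  m$requires_encounter <- isTRUE(m$requires_encounter)
  m$sex <- m$sex %||% NA_character_
  m$conditions <- m$conditions %||% list()
  m$exclusions <- m$exclusions %||% list()
  m$numerator <- m$numerator %||% list()
  if (is.null(m$age) || m$age$min > m$age$max) {
    stop(sprintf("measure %s: invalid age range", m$id %||% "?"))
  }
  used <- c(
    vapply(m$conditions, `[[`, character(1), "concept"),
    unlist(lapply(m$exclusions, `[[`, "concepts")),
    unlist(lapply(m$numerator, `[[`, "concepts")),
    if (m$episodic) c(m$episode$dx_concept, m$episode$antibiotic_concepts,
                      m$episode$test_concepts)
  )
  unknown <- setdiff(used, registry$concept)
  if (length(unknown) > 0) {
    stop(sprintf("measure %s references unregistered concept(s): %s",
                 m$id, paste(unknown, collapse = ", ")))
  }
  structure(m, class = "fqm_measure")
}

#' @export
print.fqm_catalog <- function(x, ...) {
  cat(sprintf("Measure catalog: %d measures\n", length(x)))
  for (m in x) {
    tags <- c(if (m$inverse) "inverse", if (m$episodic) "episodic")
    cat(sprintf("  %-7s %s%s\n", m$id, m$label,
                if (length(tags)) paste0(" [", paste(tags, collapse = ", "), "]") else ""))
  }
  invisible(x)
}

#' @export
print.fqm_measure <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$id, x$label))
  cat(sprintf("  ages %d-%d%s%s%s\n", x$age$min, x$age$max,
              if (!is.na(x$sex)) paste0(", ", x$sex) else "",
              if (x$inverse) ", inverse" else "",
              if (x$episodic) ", episodic" else ""))
  invisible(x)
}

# Resolve a catalog window spec to an integer day interval [lo, hi].
window_bounds <- function(window, period) {
  end <- as.integer(period$end)
  switch(window$type,
    mp = c(as.integer(period$start), end),
    ever = c(-.Machine$integer.max, end),
    before_mid = c(-.Machine$integer.max, as.integer(period$mid)),
    before_end = {
      lo <- period$end
      if (!is.null(window$years)) lo <- shift_years(lo, -window$years)
      if (!is.null(window$months)) lo <- shift_months(lo, -window$months)
      if (!is.null(window$days)) lo <- lo - window$days
      c(as.integer(lo), end)
    },
    stop(sprintf("unknown window type '%s'", window$type))
  )
}
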