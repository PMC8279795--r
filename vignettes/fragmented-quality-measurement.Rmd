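---
title: "Methods: quality measurement under care fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality measurement under care fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragqm)
```

## The measurement problem

Ambulatory eCQMs are defined over a measurement period (here a calendar
year) by three layers of logic: a *denominator* (who the measure applies
to — age and sex gates, required diagnoses, a qualifying encounter), a
set of *exclusions* (who is removed from measurement, e.g. hysterectomy
for cervical screening, hospice care, pregnancy), and a *numerator*
(evidence that recommended care occurred within a lookback window, or —
for value-based measures — that the most recent observation satisfies a
threshold). Every patient × measure evaluation resolves to exactly one of
four states, with strict precedence:

1. `NOT_APPLICABLE` — denominator not met;
2. `EXCLUDED` — denominator met, an exclusion applies;
3. `NONCOMPLIANT` / `COMPLIANT` — otherwise, from the raw numerator.

Two measures are *inverse*: the raw numerator event (a most recent HbA1c
above 9.0% or no test at all; a high-risk medication order in an elder)
is undesirable, so raw-met maps to `NONCOMPLIANT`. One measure is
*episodic* (pharyngitis testing in children): eligibility and compliance
are decided per episode — a pharyngitis diagnosis followed by an
antibiotic within 3 days — with an episode-level exclusion (an antibiotic
in the prior 30 days) and the patient compliant only if every qualifying
episode had a group-A strep test within ±3 days.

When the same patient is evaluated on two nested event sets — the
originating organization's records versus records from all sources — the
pair of outcomes forms a 4×4 transition table. Because all denominator
logic is *existential* (it only ever asks whether events are present),
adding data can never turn an applicable patient not-applicable; the
all-sources scope is therefore taken as the reference standard, and
"applicable" means applicable under it. Transitions are classified as
NA→NC, NA→CC, NC→CC, CC→NC, or Other (every unequal pair involving
`EXCLUDED` is pooled, since exclusion-related changes are
heterogeneous and individually rare).

## The simplified measure catalog

The 14 measure emulations (shipped declaratively in
`inst/extdata/measure_catalog.yaml`, concepts in
`inst/extdata/concept_registry.csv`) keep the structural drivers of
cross-facility discrepancy — age/sex gates, diagnosis-dependent
denominators, encounter requirements, lookback windows, exclusions,
inverse and episodic logic — while replacing licensed value sets and CQL
with controlled concept labels. Windows follow standard clinical
practice: e.g. colonoscopy within 10 years, sigmoidoscopy within 5,
mammography within 27 months, cytology within 3 years (HPV testing
within 5 from age 30), eye exam in the period or the year before,
diabetes diagnosis within 2 years of the period end, hypertension
diagnosis by mid-period. All windows, thresholds and age anchors are
plain fields in the YAML and can be overridden by pointing
`measure_catalog()` at an edited file. These emulations are structural
stand-ins, not certified measure logic; absolute compliance levels should
not be compared against published benchmark rates.

Numerical conventions: dates are calendar dates without time zones;
intervals are closed on both ends; ages are completed years at the
period-end anchor, with February-29 birthdays completing their year on
February 28 in non-leap years; "mid-period" is the floor midpoint of the
interval. Value predicates apply to the most recent in-window
observation, with same-date ties broken by a stable ordering (concept,
then values) so evaluation never depends on row order. Document
deduplication keeps the most recently received document per (patient,
facility, service date), with receipt-time ties broken by a stable
content key; deduplication is idempotent and never merges across dates or
facilities. The facility activity filter reads "more than 6 months" as
strictly greater than 6 (≥ 7 qualifying months at ≥ 100 documents);
both thresholds are arguments.

## The synthetic-data generator

Protected HIE data cannot be redistributed, so the package's study
conditions are embodied in a seeded generator
(`emulate_study_defaults()`): 21 health systems (3 facilities each) and
32 ambulatory practices (1 facility), 100 patients per organization, a
2018 calendar-year period with a 10-year lookback horizon, demographics
drawn per organization type (57.0% / 61.3% female; age bands skewing
older in health systems, giving ≈ 59.6% female overall), chronic
conditions drawn independently per prevalence, preventive and monitoring
events drawn per care probability over clinically plausible spans (so
that window arithmetic, not generation, decides compliance), and routine
encounter volumes calibrated so deduplicated documents per patient land
near 21.3 (health systems) and 19.9 (practices), ≈ 20.5 overall and
≈ 2.2–2.4 applicable measures per patient.

Fragmentation has two parameters. Each patient is *multi-facility* with
probability 0.79; each clinical fact of a multi-facility patient is
recorded externally with probability θ (default 0.464/0.79 ≈ 0.587),
at a uniformly chosen non-origin facility, so the unconditional external
fraction of records is ≈ 46% while ≈ 79% of patients have external
data. With the multi-facility rate at 1, θ is exactly the per-event
external probability (the convergence tests use this setting); with
θ = 0 no event ever leaves the originating organization, which is the
degenerate case used as a negative control throughout the tests. An
encounter is emitted alongside every clinical fact at its facility and
date, events are bundled into documents per (facility, service date),
and each document is duplicated with probability 0.05 with a later
receipt timestamp.

Deliberate simplifications, hence what passing tests do *not* show about
real data: condition assignment is independent (no comorbidity
structure); external facility choice is uniform (no referral network);
identities are given (no record linkage); events are concept-labeled
(no terminology noise); date fragmentation is independent per event
(real visits cluster services). The generator demonstrates the
*mechanism* of fragmentation-induced measurement discrepancy and
calibrates the pipeline; it does not reproduce any particular health
system's discrepancy magnitudes.

## Statistics

The paired-outcome test is Bowker's symmetry construction, the natural
multinomial extension of McNemar's test to the four outcome states:
\[ T = \sum_{i<j,\; n_{ij}+n_{ji}>0} \frac{(n_{ij}-n_{ji})^2}{n_{ij}+n_{ji}}, \]
with degrees of freedom equal to the number of contributing pairs; for
two categories this is exactly McNemar's \((b-c)^2/(b+c)\). A table with
no discordant mass has \(T = 0\) and p defined as 1. The asymptotic χ²
reference is adequate for the pooled table; per-measure tables are
sparse, so the per-measure default is a Monte Carlo test under the
exchangeable-direction null: holding each unordered pair's discordant
total fixed, every unit is reassigned to either direction with
probability ½, and \(p = (1 + \#\{T^* \ge T\})/(1 + B)\) — the +1
correction is standard resampling practice and avoids p = 0. The test is
deterministic given its seed. Across the 14 per-measure tests p-values
are adjusted by Benjamini–Hochberg step-up (delegated to
`stats::p.adjust`); the FDR procedure is a default, not a claim that
dependence between measures sharing patients is fully addressed — a
known limitation, as patients contribute several measures and
within-patient correlation is not modelled by the per-measure null.

Performance rates are CC/(CC+NC); an empty denominator is reported as
undefined (`NA`, rendered as a dash), never as zero. Net compliance
change for a measure is 100 × (all-sources rate − origin rate), the
origin rate computed over origin-applicable outcomes only, since that is
what single-EHR reporting would submit. Balanced opposite flips therefore
produce discrepancies without net change — the canonical 10-up/10-down
blood-pressure panel yields 20 discrepancies, zero net change and a zero
symmetry statistic.

## Verification design and problem sizes

The suite pairs every operation with an independent oracle: a group-by-max
deduplication oracle, a month-counting activity-filter oracle, a
hand-written per-measure brute-force evaluator (naive scans with
hard-coded 2018 window dates) compared against the engine on a ~1 050
patient population with boosted prevalences under both scopes, exact
enumeration of the Monte Carlo null for tables with ≤ 12 discordant
units, a 1 000-simulation type-I calibration of the Monte Carlo test at
α = 0.05, and a hand step-up FDR oracle. Fragmentation behaviour is
checked as a trend (mean discrepancy rate non-decreasing over
θ ∈ {0, 0.1, 0.25, 0.5}, five seeds each, 250-patient populations) and
as parameter recovery (with one diabetes diagnosis per diabetic patient
and unconditional per-event fragmentation θ = 0.3, the
newly-applicable rate of the three diabetes measures estimates θ within
simulation error, pooled over two 400-patient runs). These sizes were
chosen as the smallest at which the Monte Carlo tolerances are tight
enough to be meaningful.

## Open design choices

Where the analysis admitted more than one reasonable construction, the
package fixes and documents one: the organization (not the individual
facility) is the unit of the originating scope, matching how facilities
group into practices and health systems; per-facility event-volume
distributions beyond the per-type means are exposed as configuration
rather than asserted; the specific multinomial symmetry statistic, the
resample count, and the FDR procedure are explicit defaults with both
asymptotic and resampling p-values exposed. Receipt-time tie-breaking in
deduplication has no canonical rule; the stable content key makes the
result deterministic on pathological inputs without affecting any
realistic case.
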