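Package: fragqm
Title: Quality Measurement Under Care Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-facility ambulatory clinical data with a tunable
    care-fragmentation rate, evaluates simplified emulations of fourteen
    electronic clinical quality measures (eCQMs) under two data scopes
    (originating organization only versus all sources), classifies the
    resulting outcome discrepancies, and tests them with a multinomial
    symmetry extension of McNemar's test, Monte Carlo per-measure tests,
    and false-discovery-rate adjustment. Includes document deduplication,
    facility activity filtering, patient sampling, and a reproducible
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
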