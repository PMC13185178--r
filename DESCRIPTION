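Package: pdsentinel
Title: Site-Level Protocol Deviation Risk Monitoring for Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects investigator sites with atypical protocol-deviation
    (PD) reporting in multi-site clinical trials and characterises what is
    being deviated from. Implements a visit-matched bootstrap resampling
    null for site-level PD counts with two-tailed empirical probabilities,
    Benjamini-Hochberg false discovery rate control and convergence
    diagnostics; a hierarchical topic-merging pipeline over free-text
    deviation narratives with pluggable extraction and embedding backends
    and silhouette validation; a judge-based classification validation
    harness with Wilson score intervals; an integration layer producing
    per-site risk profiles with site-specific, country-specific or
    study-systemic scope assessment; and a synthetic portfolio generator
    with known ground truth so the whole pipeline is testable without
    operational trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
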