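Package: alirecover
Title: Roadmap-Driven Recovery of Missing Allostatic Load Components in EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operationalizing the allostatic load index (ALI) as a
    computable phenotype on electronic health record (EHR) data, and for
    recovering missing ALI components from auxiliary ICD-10 diagnoses. A
    clinician-curated "roadmap" of search terms is matched against ICD-10 code
    descriptions; patients carrying a matching diagnosis have the corresponding
    missing biomarker reclassified as unhealthy. Includes roadmap parsing,
    normalization and clinician adjudication, a self-consistency expansion loop
    with a pluggable term proposer, chart-review-versus-algorithm evaluation
    statistics (status flows, missingness summaries, disagreement taxonomy,
    engagement regression), and a synthetic EHR cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
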