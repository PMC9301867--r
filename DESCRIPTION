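Package: somaticfunnel
Title: Two-Cohort Somatic Mutation Prioritization, Spectra, and Signature Refitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing candidate cancer driver genes from annotated
    somatic mutation tables in a two-cohort (case/control) exome study. Implements
    a staged filtering funnel (known-polymorphism exclusion, transcript collapsing,
    driver-catalog retention, exclusion of previously reported genes, case-specific
    overlap, recurrence, and amino-acid-change filters), HGVS-based consequence
    classification, six-class and 96-channel (SBS96) mutation spectra, non-negative
    least-squares refitting of mutational-signature exposures against a reference
    catalog, recurrent copy-number event selection by start coordinate, and a
    synthetic two-cohort data generator with ground-truth manifests for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    purrr,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
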