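Package: ipac
Title: Quantitative Interaction Calling for Parallel Affinity-Capture SILAC Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes genuine protein-complex members from non-specific
    contaminants in affinity-purification mass-spectrometry experiments that
    combine reciprocal SILAC labelling with parallel affinity capture (iPAC).
    Reads MaxQuant-style protein-group tables, orients heavy/light ratios onto
    a common tagged/control axis, calls per-experiment significance against
    the median +/- k standard deviations of the log2 ratio distribution, and
    combines calls across replicates, reciprocal labellings and resins into
    genuine / tag-specific-artefact / non-specific verdicts with
    high/medium/low confidence ranks. Also builds contaminant ("beadome") and
    abundance ("abundome") lists from control pull-downs, including emPAI
    scoring via in-silico tryptic digestion, and ships a seeded simulator
    that generates ground-truthed synthetic datasets for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
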