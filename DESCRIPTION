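Package: strainshare
Title: Strain-Sharing Detection and Transmissibility from Per-Species Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers person-to-person microbial strain transmission from
    per-species phylogenetic trees (StrainPhlAn-style Newick output) and
    cohort metadata. Computes normalized phylogenetic distances (nGD),
    calibrates species-specific strain-identity thresholds by maximizing
    Youden's index under a false-positive bound with a percentile fallback,
    validates thresholds on FMT donor-recipient triads, calls strain-sharing
    events with a food-origin strain filter, summarises sharing rates by
    host relationship, estimates per-species transmissibility across
    transmission modes, and builds strain-sharing networks. Includes a
    synthetic-cohort generator with planted ground truth so the whole
    pipeline is testable without real metagenomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
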