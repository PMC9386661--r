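Package: duplexct
Title: Duplex Sequencing Consensus Calling, ctDNA Triage and Exact Single-Stage Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular analysis stack of a liquid-biopsy-guided
    phase II trial: simulation of duplex-tagged paired-end read libraries with
    known ground truth, tag-based read pre-processing, single-strand and duplex
    consensus assembly (SSCS/DCS) for error suppression, low-allele-fraction
    SNV/indel calling with supporting-molecule filters, focal copy-number
    log2-ratio calls, a SNP-based sample fingerprint, droplet digital PCR
    fractional-abundance computation with the zero-mutation ctDNA triage
    eligibility rule, and the exact-binomial single-stage (A'Hern) design with
    response-proportion confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
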