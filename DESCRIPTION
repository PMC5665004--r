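Package: colldigi
Title: Mass Digitisation Pipeline for Pinned-Insect Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for barcode-driven mass digitisation of
    natural history collections. From a folder tree of specimen photographs
    it crops and resizes label panels, decodes DataMatrix barcodes (a pure R
    ECC200 codec with Reed-Solomon error correction is included), renames
    files and auto-creates specimen records; supports verbatim label
    transcription with escalation flags, variant-to-master site and taxon
    normalisation with deduplication reports, frequency-ranked
    georeferencing triage with double-blind quality assurance, and
    dependency-ordered export to an (emulated) collection management system
    through to Darwin Core occurrence publication. Project analytics cover
    three-point (PERT) performance estimation from timing logs,
    completeness censuses and cost-per-specimen reporting. A seeded
    synthetic-collection generator renders ground-truthed specimen
    photographs so the whole pipeline is testable without museum data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
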