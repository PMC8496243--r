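Package: dliscan
Title: Detection of Differentially Located Insertion Sequences in
    Bacterial Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Pairwise comparison of complete or draft bacterial genome
    assemblies against a library of insertion sequences (ISs) to detect
    differentially located ISs (DLISs): sequence flanks of every detected
    IS are extracted, anchored onto the other genome by local nucleotide
    homology search, and each occurrence is classified as differentially
    located, same-location, to-verify or discarded.  Includes an IS
    insertion simulator with target-site duplications, a synthetic genome
    generator, draft-assembly fragmentation, a precision/recall evaluation
    harness and a graphical genome-context report.  Homology search runs
    through the NCBI BLAST+ blastn executable when available, with a
    deterministic built-in seed-and-extend engine as fallback.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb; optional, a
    built-in search engine is used when absent)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
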