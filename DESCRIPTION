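Package: misspR
Title: Secretome Cataloguing, Two-Speed Genome Architecture and
    Presence-Absence Polymorphism Analysis for Ectomycorrhizal Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to catalogue fungal secretomes into small secreted
    proteins (SSPs), CAZymes, lipases, proteases and other secreted
    proteins; to select mycorrhiza-induced SSP (MiSSP) effector candidates
    from differential-expression tables; to classify genes into gene-dense
    repeat-poor (GDR) versus gene-sparse repeat-rich (GSR) genome
    compartments from 5' and 3' flanking intergenic region lengths; and to
    analyse gene presence-absence polymorphism across strain panels from
    BLAST-style hit tables (coverage-based presence calls, Jaccard
    distances, principal coordinates analysis, one-way PERMANOVA,
    conservation classes against outgroups). A synthetic-data generator
    emulates the study design (bipartite genome, negative-binomial counts
    with planted fold changes, clade-structured gene deletions) with
    exported ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
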