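Package: oriSSDS
Title: Strand-Aware Classification and Characterization of Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies strand-specific short-nascent-strand (ori-SSDS)
    peaks into bidirectional and unidirectional (Crick-only / Watson-only)
    replication origins, profiles replication fork direction (RFD) around
    them from Okazaki-fragment (OK-seq) reads, and quantifies strand-specific
    G4-quadruplex and genomic/epigenomic feature associations against
    length-matched randomized controls. Ships a fully specified synthetic
    study generator (genome, origin map, stranded SNS and OK-seq reads,
    feature tracks) with truth labels so every analysis stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
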