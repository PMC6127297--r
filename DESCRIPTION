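Package: blockprimr
Title: Blocking-Primer Design and In Silico Specificity for Host-Depleted
    18S Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and evaluation of blocking primers that suppress host
    (Scleractinia) 18S rRNA amplicons in eukaryotic metabarcoding. Partitions
    a taxonomy-annotated reference database into host and metazoa-free sets,
    performs degenerate (IUPAC-aware) in silico PCR to extract amplicons,
    stacks anchored amplicon 3'-tails, profiles per-column Shannon entropy,
    enumerates blocking-primer candidates under length/overlap/melting
    temperature constraints, and scores their in silico specificity per taxon
    group. Also provides the downstream community statistics used with such
    data: similarity-threshold clade annotation of symbiont OTUs, coverage and
    presence filters, genus aggregation, Pielou evenness, Fisher exact tests of
    region association with Bonferroni correction, patristic distances, and
    seeded Mantel tests. Includes seeded synthetic-data generators with planted
    ground truth for every step.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
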