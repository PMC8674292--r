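Package: psiexon
Title: Pseudoexon Discovery and Splicing-Modifier Analysis from Junction Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Junction-level analysis of small-molecule splicing modifiers
    that activate premature-stop pseudoexons (psiExons). Implements the
    junction expression index (JEI) for targeted amplicon panels,
    percent-spliced-in (PSI) statistics with Fisher exact testing and
    inclusion/skipping event calling, classification of unannotated
    (pseudo)exons, maximum-entropy-style and position-weight-matrix splice
    site scoring, a genome-wide scan for AGAgtaag-donor pseudoexon
    candidates inside annotated introns, nonsense-mediated decay (NMD)
    classification of included exons, k-mer enrichment at 5' splice sites,
    and the assay arithmetic used to quantify protein lowering, qPCR
    abundance, transwell permeability and unbound brain partitioning. A
    synthetic-data module generates genomes, annotations, junction tables
    and assay fixtures with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
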