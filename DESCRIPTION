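Package: MicroDiv
Title: Coding-Region Discrimination from SNP-Level Microdiversity in Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discriminates protein-coding from noncoding open reading frames
    (ORFs) in viral genomes using within-population single-nucleotide
    microdiversity. Every SNP allele observed among reads or closely related
    sequences mapped to a reference genome is classified, for every ORF it
    falls in, as synonymous or nonsynonymous, and nonsynonymous changes are
    split by their BLOSUM62 substitution score. Per-ORF pN/pS and pNeg/pS
    ratios then separate ORFs under purifying selection (true genes, ratio at
    or below 1) from random noncoding ORFs, with dedicated rules for
    opposite-strand mirror artifacts, overprinted genes, and erroneous start
    positions. Includes a six-frame ORF finder for linear and circular
    genomes, a minimal pileup-based SNP caller, a seeded population
    simulator for validation, tab-separated result tables, and a multi-track
    SVG genome report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MicroDiv-package.R'
    'classify.R'
    'decisions.R'
    'io.R'
    'orfs.R'
    'pileup.R'
    'pipeline.R'
    'scoring.R'
    'simulate.R'
    'svg.R'
    'utils.R'
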