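Package: tnseqr
Title: Gene Essentiality and Protein-Occlusion Analysis for Transposon
    Insertion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of hypersaturated transposon insertion sequencing
    (Tn-Seq) landscapes on circular bacterial chromosomes. Computes
    insertion-density statistics per gene (IPKM and its end-curated
    variant ecIPKM, plus the classical insertion index), calibrates an
    essentiality cutoff against a reference essential-gene set, and tests
    whether protein-bound genomic regions (for example nucleoid-associated
    protein footprints from ChIP-Exo) are depleted of insertions relative
    to a bootstrap null of random same-sized regions. Includes a
    synthetic-data generator with known ground truth so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'essentiality.R'
    'genome.R'
    'landscape.R'
    'pipeline.R'
    'profiles.R'
    'protection.R'
    'synthetic.R'
    'tis.R'
    'tnseqr-package.R'
    'utils-internal.R'
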