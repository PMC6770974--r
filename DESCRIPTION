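Package: famevo
Title: Gene-Family Evolution, Expression and Domestication-Sweep Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide gene-family analysis toolkit built around the
    multicopper-oxidase (laccase) family workflow: family identification by
    domain architecture from annotation plus precomputed domain hits,
    neighbor-joining phylogeny with bootstrap and reference-anchored class
    assignment, synteny-block detection with tandem/segmental duplication
    typing, Nei-Gojobori (1986) Ka/Ks with whole-genome-duplication binning
    and molecular dating, FPKM-based expression-pattern classification
    (constitutive, tissue-specific tau, infection response, 2^-ddCt), and a
    two-population sliding-window nucleotide-diversity (pi-ratio) selective
    sweep scan. Ships deterministic synthetic-data generators with ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, Phylogenetics, SNP, GeneExpression, WholeGenome
Config/testthat/edition: 3
RoxygenNote: 7.3.3
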