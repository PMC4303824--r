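Package: ReGenEvo
Title: Three-Clade Conservation and Selection Analysis of Remaining Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses the evolutionary fate of protein-coding genes shared by
    plants, fungi and metazoans, such as the metazoan "remaining genes" of
    essential-amino-acid biosynthesis pathways. Given a protein multiple
    alignment, the underlying coding sequences and a clade assignment, the
    package computes inter-clade BLOSUM62 conservation profiles smoothed by a
    directional exponential low-pass filter, pairwise Ka/Ks by Nei-Gojobori
    (1986) counting on back-translated codon alignments with clade-pair
    averaging, neighbor-joining trees on Kimura-corrected protein distances
    with topology classification (Tree-of-Life-like, autotrophic paraphyly,
    fungi outgroup) and metazoa-fungi over fungi-plant branch-length ratios,
    and combines the three signals into a per-gene Tree-of-Life versus
    non-Tree-of-Life verdict. A codon-level simulator of three-clade families
    under neutral-to-purifying selection, with optional metazoan rate
    acceleration, provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Phylogenetics, Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
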