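Package: olfactoR
Title: Fine-Scale Evolutionary Analysis of Olfactory Receptor Gene Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for fine-scale analysis of single-family olfactory receptor
    (OR) gene repertoires from amplicon sequencing, developed around the African
    mole-rat (Bathyergidae) OR7 family. Classifies OR amplicons as putatively
    functional genes or pseudogenes from open-reading-frame disruptions and
    receptor motifs, merges sequencing and allelic variants into unique genes
    under hierarchical identity thresholds with tree-based resolution of
    ambiguous cases, maps amino-acid variability onto a seven-transmembrane
    receptor topology including ligand-binding pocket statistics, computes
    counting-based selection statistics (Nei-Gojobori dN/dS, codon-based Z
    tests, a per-codon selection scan, the ZZ linkage-disequilibrium statistic,
    Benjamini-Hochberg and Storey q-value corrections), builds
    neighbor-joining trees with bootstrap support and extracts well-supported
    clades, compares pseudogene proportions across ecological groups, and
    includes a birth-and-death gene-family simulator producing ground-truthed
    test repertoires.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
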