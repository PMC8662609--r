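Package: hotspotsym
Title: Homolog Symmetry of Meiotic Recombination Hotspots in Hybrid Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for allele-specific DMC1-SSDS and H3K4me3
    ChIP-seq signal in F1 hybrid mice. Reads are assigned to their
    chromosome homolog of origin at strain-distinguishing SNPs, hotspot
    peaks are called from strand-resolved coverage, each hotspot is
    attributed to the PRDM9 allele that activates it, and the per-hotspot
    B6-homolog read fraction is estimated with a misclassification-aware
    binomial model to classify hotspots as matched (both homologs bound)
    or evolutionarily eroded (one homolog dominates). Phenotype analysis
    relates autosomal synapsis rates to sperm production through a
    threshold ("cliff-edge") step model. A synthetic-data generator
    emulating erosion of PRDM9 binding sites makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
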