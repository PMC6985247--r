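Package: g4utr
Title: Selective Constraint and Functional Enrichment of UTR G-Quadruplexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and population-genetic analysis of putative
    G-quadruplex (pG4) motifs in mRNA untranslated regions. Scans UTR
    sequences for the canonical four-tract G4 motif, projects motifs to
    genomic coordinates and partitions them into G-tracts and loops;
    classifies genes by constitutive versus alternative pG4 isoform
    inclusion; quantifies selective constraint with allele-frequency
    comparisons, a mutability-adjusted proportion of singletons (MAPS)
    model with methylation-binned CpG rates, and a heptamer-context
    observed/expected substitution model with bootstrap and empirical-null
    inference; tests functional enrichment of cis-eQTLs, CLIP-seq binding
    sites, knockdown differential expression and ClinVar variants; and
    fits a beta-binomial model of allelic imbalance with a likelihood
    ratio test against the unbiased null. A synthetic-data generator with
    known ground truth exercises every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, Transcriptomics, StatisticalMethod
RoxygenNote: 7.3.3
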