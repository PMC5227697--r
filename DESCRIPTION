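Package: ednaFish
Title: Environmental DNA Metabarcoding Pipeline for Coastal Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for fish environmental DNA (eDNA)
    metabarcoding surveys built around short hyper-variable 12S rRNA
    amplicons. Raw paired-end reads are quality-trimmed, merged, length- and
    ambiguity-filtered, screened for bimeric chimeras and stripped of
    fish-universal (MiFish-type) primers; surviving inserts are dereplicated,
    assigned to species against a reference database with HIGH/MODERATE/LOW
    confidence classes, clustered into species-level OTUs and curated against
    a local checklist. Negative-control (blank) reads drive both removal of
    contaminant sequences and derivation of a per-sample read-fraction
    detection cut-off. The resulting station x layer x PCR-replicate
    detection matrix feeds community statistics: replicate accumulation,
    incidence-based Chao1 richness with replicate singletons/doubletons,
    surface/bottom partitioning, Bray-Curtis Mantel correlograms, sample-based
    rarefaction and detection rate/efficiency against underwater visual
    censuses. A fully seeded synthetic-data generator emulates a bay-wide
    MiSeq survey (47 stations x 2 depth layers x 3 PCR replicates plus
    blanks) with known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
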