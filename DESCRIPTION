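Package: EukRecover
Title: Decision Layer for Recovering Eukaryotic Proteins from Soil
    Metagenome Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the decision layer of a eukaryote-aware
    re-annotation pipeline for soil metagenome assemblies: contig quality
    filtering by length or gene count, selection of contigs classified
    inside Eukaryota from k-mer classifier output, phylogeny-aware
    two-pass assignment of ab initio gene-prediction model species,
    score-margin last-common-ancestor taxonomic annotation of predicted
    proteins against an NCBI-taxdump-dialect taxonomy, confirmation of
    eukaryotic contigs by a majority-of-eukaryotic-proteins rule,
    extraction of orphan proteins lacking traceable homology, and the
    quantitative comparison metrics (protein length summaries, intron
    statistics, BUSCO aggregation with paired tests, cluster-table
    bookkeeping) used to validate such re-annotations. A deterministic
    synthetic-community generator emulates every consumed file format so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Metagenomics, Annotation, Classification, GenePrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
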