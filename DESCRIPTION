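Package: hadalvirome
Title: Community Assembly Null Models, Virus-Host Linkage, and
    Microdiversity Metrics for Sediment Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological and evolutionary analysis of viral
    communities recovered from deep-sea sediment metagenomes.  Implements
    the phylogenetic (beta-nearest-taxon index) and taxonomic
    (Bray-Curtis Raup-Crick) null models that partition community
    assembly into five processes; four evidence channels for virus-host
    linkage prediction (nucleotide homology, shared tRNAs, CRISPR spacer
    matches, and d2* oligonucleotide-frequency distance) together with
    rules for integrating them into per-virus host assignments; curation
    filters for candidate auxiliary metabolic genes and lysogeny-based
    lifestyle calls; and gene-level microdiversity metrics (SNV density
    and pN/pS) computed from per-site nucleotide pileup profiles.  A
    seeded synthetic-data layer generates abundance tables, phylogenies,
    genomes, and pileups with known ground truth so that every stage of
    the pipeline can be validated end to end without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    geosphere,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
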