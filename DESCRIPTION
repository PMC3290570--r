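Package: ribomosaic
Title: Expansion Segment Polymorphism Analysis of rDNA Clone Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects hypervariable block loci (expansion segment
    polymorphisms, ESPs) in clone libraries of ribosomal marker genes,
    calls discrete block alleles per locus, assigns each clone a
    combinatorial ribotype, and quantifies the ribotype distribution:
    theoretical combination space, per-specimen richness, allele
    prevalence tests, clone-vs-ribotype rarefaction and correlation, PCR
    chimera flagging and a multi-allelic locus-pair compatibility test
    for recombination signal. Includes a clone-library simulator with
    hybridized parental ribotype clusters, SNP noise and PCR chimeras
    that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'CloneLibrary-methods.R'
    'LocusSet-methods.R'
    'core-model.R'
    'esp-stats.R'
    'io.R'
    'locus-detection.R'
    'recombination.R'
    'ribotyping.R'
    'pipeline.R'
    'ribomosaic-package.R'
    'simulate.R'
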