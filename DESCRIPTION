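Package: plastGWAS
Title: Genome-Wide Association Mapping of Phenotypic Plasticity Under
    Contrasting Environments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative framework for dissecting the genetic
    architecture of phenotypic plasticity in inbred crop panels grown
    under two contrasting environments (well-watered versus
    water-limited).  Provides simulation of multi-family recombinant
    inbred genotype panels with planted main-effect, environment-specific
    and antagonistic QTLs; five plasticity estimators (environment means,
    WW/WL ratio, relative distance plasticity index, coefficient of
    variation, Finlay-Wilkinson slopes); REML variance decomposition with
    trait-retention rules; marker quality control, kinship, PCA and
    linkage-disequilibrium decay; four genome-wide association scan
    families (kinship mixed model, iterative multi-locus, random-forest
    and gradient-boosting importance with permutation nulls); two-stage
    consensus retention across estimators and methods; and downstream
    functional annotation (region classification against GFF3, GO
    overrepresentation, karyogram export, allele-direction analysis of
    antagonistic pleiotropy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    lme4,
    ranger,
    xgboost,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudies, QualityControl, Annotation,
    LinkageDisequilibrium, SNP
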