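Package: sleclust
Title: Integrative Phenotypic and Epigenomic Subtyping of Systemic Lupus
    Erythematosus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers clinical subtypes of systemic lupus erythematosus from
    binary ACR classification criteria by multiple correspondence analysis and
    K-means clustering with bootstrap Jaccard stability selection, then
    characterises the subtypes molecularly: covariate-adjusted per-CpG ANOVA
    for cluster-associated differential methylation, cis-meQTL scanning with
    genotype quality control (MAF, Hardy-Weinberg exact test, LD pruning),
    causal-inference (mediation) testing of genotype-methylation-cluster
    triplets, gene-set / chromatin-state / ethnicity-permutation enrichment,
    and random-forest transfer of subtype labels to external cohorts. A
    fully-labelled synthetic cohort generator provides the statistical
    structure the pipeline assumes so that every stage can be exercised and
    calibrated without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
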