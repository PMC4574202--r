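Package: cafeQG
Title: Quantitative Genetics of Mean and Micro-Environmental Variance of
    Food Intake in Inbred Line Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for capillary feeder (CAFE) assays of food
    intake measured on panels of inbred Drosophila lines. Reduces vial-level
    assay data to evaporation- and survivor-adjusted per-fly intake,
    estimates among-line, sex-by-line and within-line variance components by
    restricted maximum likelihood, computes broad-sense heritabilities and
    the cross-sex genetic correlation, tests genetic heterogeneity of
    micro-environmental variance (Levene and Brown-Forsythe tests, CV_E),
    performs covariate- and relatedness-adjusted genome-wide association for
    both the mean and the coefficient of environmental variation of intake
    with kilobase-window gene annotation, and provides the statistics used
    for functional validation (Dunnett many-to-one tests, pairwise Levene
    tests, SNP-cross t-tests, effect-size attenuation reports). A seeded
    synthetic-data generator reproduces the statistical structure of a
    line-panel feeding study so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    multcomp,
    mvtnorm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
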