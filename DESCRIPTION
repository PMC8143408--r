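Package: octmorph
Title: Morphological Phenotyping of Macular OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, simulation-backed pipeline for retinal morphology
    analysis from macular optical coherence tomography (OCT) volumes:
    segmentation of the inner limiting membrane (ILM) and Bruch's membrane (BM)
    by running-median smoothing and point-of-interest detection, total retinal
    thickness maps, scan quality-control indicators and cohort
    inclusion/exclusion rules, Macula 6 grid and spline-based central foveal
    thickness phenotypes, genotype-stratified thickness maps, additive-model
    SNP association, and two-sample Mendelian randomisation (inverse-variance
    weighted and MR-Egger). A synthetic-data module generates ground-truthed
    OCT volumes, cohorts and GWAS summary statistics so that every stage of the
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
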