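Package: flyscreen
Title: Hit Calling, Modifier Analysis and Oligogenic Risk Scoring for a
    Drosophila CNS Phenotyping Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for a loss-of-function screen of
    Alzheimer's-disease risk gene homologs in Drosophila: hit calling for
    brain histology (vacuole counts), electroretinogram neurophysiology
    (trace feature extraction with Kruskal-Wallis/Dunn comparisons) and
    heat/bang stress resilience (screen-then-replicate design); longitudinal
    mixed-effects analysis of climbing-speed decline in amyloid-beta and tau
    models with an area-between-curves modifier statistic and Holm-adjusted
    effect tests; integration of assay calls into gene-level phenotype
    profiles and cluster-to-SNP maps; and per-individual oligogenic risk
    scores with PCA-based cohort stratification. Includes a seeded synthetic
    data generator for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    pbkrtest,
    purrr,
    rlang,
    readr,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
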