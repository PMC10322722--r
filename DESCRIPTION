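Package: alkanox
Title: Stoichiometry, Kinetics and Expression Analysis for Syntrophic
    Alkane-Oxidizing Sulfate-Reducing Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of anaerobic cultures that couple the
    complete oxidation of mid-chain n-alkanes (pentane to tetradecane) to
    sulfate reduction. Provides the balanced electron-conserving
    stoichiometry of sulfate-coupled alkane oxidation and the predicted
    ratio of dissolved inorganic carbon production to sulfate reduction,
    inversion of that model to estimate the fraction of alkane carbon
    assimilated into biomass, hydrogen-equivalent electron loads,
    exponential activity doubling-time estimation from sulfide time
    series with dilution-event bookkeeping, a sustained-activity
    classifier for substrate-range tests, gene-length (fragments per
    kilobase) and centred-log-ratio normalization of metatranscriptome
    count tables with rRNA exclusion and expression ranking, CxxCH
    haem-binding motif scans of protein sequences, evaluation of
    rRNA-targeted oligonucleotide probes against target and non-target
    sequence sets, and seeded generators of synthetic culture, count and
    sequence data with the statistical structure each analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
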