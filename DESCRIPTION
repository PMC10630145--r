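Package: dfeload
Title: Distribution of Fitness Effects and Genetic Load from Site
    Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the distribution of fitness effects (DFE) of new
    mutations from unfolded site frequency spectra of 0-fold (selected)
    and 4-fold (neutral) degenerate sites under a Poisson random field
    model, with a gamma deleterious and exponential beneficial component,
    nuisance distortion parameters, ancestral-misidentification
    correction, AIC model averaging, bootstrap confidence intervals and
    shared-versus-independent likelihood-ratio tests. Also provides
    maximum-likelihood ancestral-allele polarization from outgroup states
    under a Kimura two-parameter model, hypergeometric SFS projection,
    nucleotide diversity ratios, Hudson's FST, and the Rxy and R'xy
    derived-allele load statistics with a weighted block jackknife, plus
    synthetic-data generators with known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
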