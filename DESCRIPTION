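Package: paleostrat
Title: Admixture, Kinship and Social-Stratification Inference from Ancient DNA Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of low-coverage ancient DNA
    pseudo-haploid genotype data: EIGENSTRAT-style input/output, block-jackknifed
    f3/f4 statistics and Hudson FST, two-source qpAdm-style admixture-proportion
    estimation with qpWave-style cladality tests, X-versus-autosome sex-biased
    admixture decomposition, pairwise-mismatch kinship classification with a
    binomial test for cross-cemetery relative pairs, admixture dating from the
    exponential decay of ancestry covariance along the genome, uniparental
    haplogroup summaries, and projection principal component analysis. Includes
    a seeded synthetic-data generator producing admixed cohorts with sex-biased
    ancestry, dated ancestry-tract mosaics and planted relatives for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
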