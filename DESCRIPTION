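Package: paleostruct
Title: Population Structure and Demography from Low-Coverage Ancient DNA
Version: 0.1.0
Authors@R:
    person("Paleostruct", "Developers", email = "maintainer@paleostruct.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for population-genetic analysis of
    low-coverage, pseudohaploid ancient-DNA genotype panels. Implements
    block-jackknifed f-statistics with a consistent f2-basis estimator that
    maximizes usable coverage under missing data, rank tests for the number
    of ancestry streams, mixture-proportion fitting by generalized least
    squares, an independent-mixture residual model of excess relatedness
    with an isolation-by-distance decay fit, kin detection from allele
    mismatch rates, and recent effective population size inference from
    runs of homozygosity called with a genotype-likelihood HMM. Ships a
    synthetic-data generator emulating capture-panel genotypes with
    realistic coverage, three-way ancestry clines and hierarchical shared
    drift, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
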