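Package: cgmwgp
Title: Crop Growth Model Informed Whole-Genome Prediction by Approximate
    Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction of maize grain yield in which a
    deterministic daily-timestep crop growth model is embedded in an
    approximate Bayesian computation (ABC) rejection sampler. Four
    physiological traits (total leaf number, area of the largest leaf,
    solar radiation use efficiency and thermal units to maturity) are
    treated as latent linear functions of SNP marker effects; marker
    effects are estimated by comparing simulated to observed yields.
    Includes a biparental doubled-haploid population simulator (Haldane
    meiosis, hidden QTL architecture, heritability-calibrated phenotypes),
    a synthetic weather generator, a GBLUP benchmark with spectral REML,
    and an experiment driver for observed- and new-environment prediction
    accuracy under genotype-by-environment interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
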