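Package: bmdrisk
Title: Benchmark-Dose Modelling and Risk Characterization for Continuous
    Genotoxicity Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmark-dose (benchmark-concentration) analysis of
    continuous genotoxicity dose-response data such as micronucleated
    reticulocyte frequencies: exponential and Hill model families
    parameterised in the critical effect dose, lognormal likelihood for
    per-animal or group-summary data, covariate-combined maximum-likelihood
    fitting across comparable studies with AIC structure selection, and
    profile-likelihood confidence limits (BMCL/BMCU). Downstream
    risk-characterization arithmetic converts the animal point of
    departure to human-equivalent values, composes assessment factors into
    acceptable daily exposure ranges and compares them with exposure
    estimates. Includes a lognormal study simulator emulating benzene-like
    inhalation micronucleus designs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
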