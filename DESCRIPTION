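Package: rwdemog
Title: Stage-Structured Demography and Calving Trends of Right Whales
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the recovery of North Atlantic right whales
    (Eubalaena glacialis) against Southern right whale benchmarks. Builds a
    three-stage (calf, immature, adult) female projection matrix from annual
    survival rates, stage durations and the calving interval; computes the
    asymptotic growth rate, stable stage distribution, reproductive values,
    sensitivities and elasticities; runs seeded, demographically stochastic
    multi-year projections with ensemble summaries; fits negative-binomial
    log-link GLMs to annual calf-count panels with per-population slopes and
    FDR-adjusted pairwise slope contrasts; and generates synthetic calf-count
    panels with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
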