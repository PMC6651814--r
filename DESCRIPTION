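Package: lodsim
Title: Polygenic Risk, Aging Coefficients, and Lifetime Risk of Late-Onset Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population simulator for polygenic late-onset diseases under a
    proportional-hazards model with a multiplicative genetic architecture.
    Builds model SNP architectures on a minor-allele-frequency by odds-ratio
    grid, samples Hardy-Weinberg populations of multiplicative polygenic risk
    scores, and inverts a clinical yearly incidence curve to recover the
    per-age "aging coefficient" that maps risk score to diagnosis probability.
    The recovered coefficient is then used to project incidence density,
    cumulative incidence and lifetime risk under competing Gompertz-Makeham
    mortality, across hazard-ratio grids, life-expectancy extensions, and
    prophylactic gene-therapy scenarios that lower the population risk score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
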