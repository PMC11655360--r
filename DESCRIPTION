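Package: bwasdesign
Title: Study Design Optimization for Brain-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and analysing brain-wide association studies
    (BWAS). Estimates the robust effect size index (RESI) and its
    cross-sectional equivalent (CS-RESI) from cross-sectional linear models
    and longitudinal marginal models fitted by generalized estimating
    equations with an exchangeable working correlation; builds targeted
    sampling weights (bell, uniform, U-shaped between-subject targets and
    decreasing, uniform, increasing within-subject targets) for
    weighted-bootstrap design experiments; converts effect sizes into power,
    replicability and required sample size via the non-central F
    distribution; decomposes between- and within-subject covariate effects;
    and meta-regresses study-level effect sizes on design features with
    inverse-SE weights and robust standard errors. Includes a synthetic
    multi-study cohort generator so every stage is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    sandwich,
    jsonlite,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
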