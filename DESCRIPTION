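Package: dnmjoint
Title: Joint Mixture-Model Analysis of De Novo Mutation Counts Across Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-level burden analysis of de novo mutations (DNMs) observed
    in parent-offspring trio cohorts for one or two traits. Per-gene DNM
    counts are modelled as a Poisson mixture over latent risk classes, with
    expected null counts 2*N*mu driven by gene mutability and cohort size,
    and relative risk in risk genes linked to functional annotations through
    an exponential link. Parameters are estimated by an
    expectation-maximization algorithm with closed-form or Newton-Raphson
    M-steps; risk genes are identified by thresholding the joint local false
    discovery rate so that the global false discovery rate is controlled.
    Includes variant-to-gene annotation collapsing with two-stage feature
    selection, and a simulation engine for power, error-rate, and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
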