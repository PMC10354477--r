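Package: kincomp
Title: Kinship Composition of Same-Sex Social Units from Pedigree Data
Version: 0.1.0
Authors@R: person("kincomp", "maintainers", email = "kincomp@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the kinship composition of animal social
    units: pedigree-based relatedness coefficients, a two-generation
    categorical kin/non-kin criterion for same-sex dyads, group-level
    composition labels (related, unrelated, mix-related) with a continuous
    proportion-of-kin-dyads alternative, and a genetic-cluster rule for
    classifying units from noisy marker-style relatedness estimates.
    Includes forward-time social-unit pedigree simulators with known
    ground-truth composition, a packaged species-level comparative dataset,
    and from-scratch comparative machinery: symmetric two-state Mk
    likelihoods, stochastic character mapping by uniformization, and
    Bayesian phylogenetic Bernoulli regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
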