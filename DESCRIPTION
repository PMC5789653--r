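Package: equipoint
Title: Equilibrium-Point Models of Endocrine Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting set-point and equilibrium-point models of
    homeostatic regulation in negative-feedback endocrine systems
    (calcium/PTH, glucose/insulin, FT4/TSH). Provides a fixed-point solver
    for monotone feedback loops, seeded Monte-Carlo cohort simulators under
    both regulation models, a correlation-sign consistency evaluator with a
    bundled table of published cohort correlations, and a thermostat-free
    radiator-house analogy with a two-towns experiment reproducing the
    opposite temperature-energy correlation signs of the two regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
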