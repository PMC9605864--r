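Package: scco2
Title: Probabilistic Social Cost of Carbon Dioxide Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular integrated assessment engine for estimating the social
    cost of carbon dioxide (SC-CO2). Couples a calibrated probabilistic
    generator of joint population, GDP and greenhouse-gas emission
    trajectories (2020-2300) to an impulse-response climate emulator with a
    state-dependent carbon cycle, a component-based sea-level model with an
    Antarctic fast-disintegration threshold, four sectoral damage models
    (temperature-related mortality valued with an income-scaled value of a
    statistical life, agriculture, building energy expenditures, and
    least-cost coastal adaptation against storm-surge risk), and stochastic
    Ramsey discounting. The SC-CO2 is computed by Monte Carlo pulse
    experiments: paired model runs differing only by a small CO2 emission
    pulse, with discounted marginal damages normalized per tonne of CO2 and
    decomposed by sector.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
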