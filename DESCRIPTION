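Package: magnetea
Title: Techno-Economic Simulation of Industrial Magnetosome Production
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bioprocess mass balance and techno-economic analysis for
    industrial production of biological-origin magnetite nanoparticles
    (magnetosomes, BMNs) by Magnetospirillum gryphiswaldense MSR-1.
    Simulates the inoculum train, single-stage fed-batch and semicontinuous
    fermentation, and the downstream recovery cascade (high-pressure
    homogenization, magnetic separation columns, disk-stack centrifugation);
    converts batch recipes into annual schedules; assembles factored capital
    and annual operating costs; determines minimum selling prices at a fixed
    payback time by bisection; and runs one-at-a-time sweeps and seeded
    Monte-Carlo scenario ensembles for sensitivity analysis. Ships two
    calibrated base-case plant configurations and a validated scenario
    configuration format with per-parameter provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
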