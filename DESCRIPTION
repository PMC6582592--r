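Package: vegtrans
Title: State-and-Transition Simulation of Vegetation Dynamics with
    Learned Transition Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating vegetation dynamics as transitions
    between discrete states defined by species composition, canopy
    height and leaf area index. Transition timing and target states are
    predicted by a two-headed classifier (a configurable multilayer
    perceptron or an empirical lookup model) trained on per-cell annual
    trajectories, and ecosystem attributes such as live tree carbon and
    tree species diversity are linked to state-by-residence-time classes
    through an empirical attribute database. Includes a synthetic
    succession simulator with a known semi-Markov transition kernel for
    end-to-end testing and parameter-recovery experiments, a raster
    simulation engine operating on a 100 m grid with an annual time
    step, and readers and writers for the plain-text formats involved.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    digest,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
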