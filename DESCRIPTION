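Package: wavemem
Title: Decay-Amplify Working Memory in Noisy Rate Networks
Version: 0.1.0
Authors@R:
    person("Wavemem", "Developers", email = "wavemem@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a working-memory mechanism
    in which an analog stimulus variable is stored by a noisy, imperfectly
    tuned rate network as a travelling activity pulse. Activity decays
    during the first part of the delay period and is re-amplified when an
    externally timed executive input gates a block of late cells whose
    feedback restores the stimulus-indicative level. Provides
    Euler-Maruyama simulators for a feed-forward chain and a
    symmetric-kernel field model, the closed-form tuning theory
    (line-attractor coupling bound, piecewise-exponential decay-amplify
    envelope, admissible executive-input timing interval), trial analyses
    (monotonic-encoding classification into early, persistent and late
    cells, wavefront tracking, comparison-phase readout), and scripted,
    seeded Monte-Carlo experiments behind a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
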