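Package: aquaflux
Title: Water Channel Gating and Single-Channel Permeability Analysis from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Aquaflux", "Developers", role = c("aut", "cre"),
    email = "maintainers@aquaflux.dev")
Description: Trajectory-analysis toolkit for water channel (aquaporin) gating
    studies: PDB/DCD trajectory input and output, geometric order parameters
    (minimum-image distances and proper dihedrals), discrete gating-state
    classification with hysteresis and dwell-segment extraction, water
    permeation event counting, diffusive (p_d) and osmotic (p_f)
    single-channel permeability estimation from the collective water
    displacement coordinate, the single-file continuous-time-random-walk
    consistency check p_f/p_d = N+1, and HOLE-style maximal-sphere pore
    radius profiles.  Includes synthetic-data generators (single-file
    hopping/Brownian water columns, telegraph order-parameter series, toy
    pore geometries, a minimal gating fixture) with known ground truth so
    every analysis stage is testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
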