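Package: veildyn
Title: Hydrodynamics and Collective Dynamics of Stalk-Tethered, Veil-Forming Microbes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the low-Reynolds-number hydrodynamics of microbial cells
    that anchor to a boundary with a mucous stalk and collectively weave a
    veil: closed-form prolate-spheroid resistance functions, the stokeslet
    image system beneath a no-slip wall, the orientation dynamics and
    stability of a tethered cell (including the critical stalk length),
    and the advection-versus-diffusion scalings that set the minimum
    propulsive force of a filter feeder.  Also provides synthetic-data
    generators emulating stalk-elongation tracks, an oxygen-consuming
    chemotactic chamber with Stern-Volmer fluorescence imaging, and veil
    scattered-light series, together with the measurement pipeline
    (elongation-rate fits, oxygen-map inversion, frame-difference cell
    density, front detection, veil-production fits) that recovers the
    generating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
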