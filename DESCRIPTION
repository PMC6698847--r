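Package: memchrom
Title: Zonal Rate Modeling of Membrane Chromatography Modules and
    Continuous Capture Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of radial-flow membrane chromatography
    modules using a five-zone general-rate ("zonal") model with flow
    splitting and merging, lumped mass-transfer kinetics and salt-dependent
    competitive Langmuir isotherms.  Includes tracer residence-time-
    distribution moment analysis with closed- and open-vessel Danckwerts
    dispersion inversion, batch-adsorption isotherm interpretation and
    least-squares fitting, orchestration of batch, sequential
    (counter-current loading) and integrated counter-current (iCCC)
    operation, and a batch-versus-continuous performance case-study engine
    (capacity, productivity, eluent consumption, pressure constraints).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
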