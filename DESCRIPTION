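Package: gravicreep
Title: Microrheology and Gravitational Creep Analysis of Nuclear Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the mechanics of soft intranuclear
    networks and the slow gravitational sedimentation of liquid-like
    nuclear bodies (nucleoli, histone-locus bodies) in giant oocyte
    nuclei. Implements the extended Kelvin-Voigt viscoelastic model
    (spring and dashpot in parallel, in series with a second dashpot)
    with its creep compliance and complex moduli; estimation of storage
    and loss moduli from magnetic-bead oscillatory and step-force
    trajectories, including Lissajous ellipse analysis and simultaneous
    weighted model fitting with bootstrap confidence intervals; 3D
    nuclear-body spatial statistics (ellipsoid normalization,
    gravitational-axis alignment, asymmetry distance, sedimentation
    displacement, density profiles, force-time collapse viscosity,
    truncated power-law size fitting, Fisher-z correlation intervals);
    a Brownian-dynamics simulator of sedimenting, coalescing particles
    under effective gravity; and seeded synthetic-data generators with
    known ground truth for every pipeline input.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
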