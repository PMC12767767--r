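Package: diffsizer
Title: Microfluidic Diffusional Sizing of Solute Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates hydrodynamic radii of solute particles (proteins and
    their complexes) from fluorescent intensity profiles recorded along the
    main channel of a microfluidic focusing device. Cross-channel profiles are
    cropped, wall-located, baseline- and area-normalized, centered, and fitted
    with bounded multistart Gaussian mixtures; the growth of the fitted squared
    width parameter over transit time is regressed to obtain diffusion
    coefficients and, via the Stokes-Einstein relation, approximate radii and
    particle-count estimates. Includes a forward Brownian-diffusion simulator
    that writes measurement workbooks with known ground truth, goodness-of-fit
    model-order scans, and diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    readxl,
    stats,
    tools,
    utils,
    yaml,
    zip
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
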