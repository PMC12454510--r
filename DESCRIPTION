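Package: periwall
Title: Interstitial Fluid Flow and Solute Transport Across the Peri-Arterial Wall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state model of interstitial fluid flow and solute transport
    across the outer layers of an artery wall (intima/media, adventitia,
    perivascular adipose tissue). Radial Darcy flow in a layered cylindrical
    annulus is coupled to distributed Starling filtration from vasa vasorum and
    a lymphatic drainage sink; non-binding solute transport is solved as a
    linear advection-diffusion equation with microvascular uptake. Includes the
    mass-balance-deviation (Lambda) parameter-refinement workflow, Monte-Carlo
    ensemble runners for healthy and atherosclerotic configurations, and the
    derived transport metrics (boundary pressures, lymph origin decomposition,
    dilution distance, concentration gradients and the dendritic-cell
    chemotaxis transport distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
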