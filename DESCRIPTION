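Package: icefield
Title: Mesoscale Phase-Field Simulation of Freeze Concentration in Protein
    Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the growth of ice crystals and the accompanying freeze
    concentration of solutes (sucrose as a model excipient) in supercooled
    aqueous solution on a periodic two-dimensional mesoscale domain. Couples a
    non-conserved phase field for the ice/solution interface (Allen-Cahn type)
    with a conserved Cahn-Hilliard equation for the solute volume fraction, a
    thermal energy equation with latent-heat release and a uniform volumetric
    cooling sink, and a quasi-incompressible low-Reynolds-number flow driven by
    the density change upon freezing and by buoyancy. Thermophysical properties
    of ice and supercooled sucrose solution (density, specific heat, thermal
    conductivity, Vogel-Fulcher-Tammann viscosity, Stokes-Einstein diffusivity,
    liquidus temperature) follow published correlations. Integration uses a
    Fourier pseudo-spectral discretization with 2/3-rule dealiasing and
    semi-implicit (stabilized) forward-Euler time stepping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
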