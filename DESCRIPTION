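Package: cpaload
Title: Cryoprotective Agent Loading Dynamics of Oocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the osmotic response of oocytes during loading and
    unloading of permeating cryoprotective agents (CPAs) such as ethylene
    glycol. Implements the two-parameter membrane transport formalism
    (independent water and solute fluxes with Arrhenius temperature scaling),
    nonlinear least-squares estimation of the hydraulic (Lp) and solute (Ps)
    membrane permeabilities from volume-versus-time traces, a synthetic
    video-microscopy trace generator for parameter-recovery studies, and a
    phenomenological coupled transient-diffusion / quasi-static elasticity
    finite-element model of a capillary-held spherical oocyte with
    concentration-dependent eigenstrain, for spatially resolved CPA
    concentration, deformation and hydrostatic pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
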