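Package: sutterby
Title: Peristaltic Transport of a Sutterby Nanofluid with Hall and Ion-Slip Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Lubrication-limit model of peristaltic transport of a Sutterby
    nanofluid through an inclined tapered channel under Hall and ion-slip
    magnetohydrodynamics, with Buongiorno thermophoresis and Brownian-motion
    slip. The coupled stream-function/temperature/concentration boundary-value
    problem is solved by a second-order homotopy perturbation cascade carried
    out in exact polynomial arithmetic, cross-validated against an independent
    finite-difference Newton collocation solver. Derived observables include
    axial velocity, shear stress, pressure gradient and pressure rise per
    wavelength, heat-transfer coefficient, Nusselt number, and streamline and
    isotherm grids. A small Levenberg-Marquardt-trained multilayer perceptron
    provides a fast surrogate for the Nusselt number over parameter sweeps.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
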