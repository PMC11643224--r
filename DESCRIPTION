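Package: spherogrowth
Title: Chemomechanical Growth-Elasticity Simulation of Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of tumor spheroids as a thermodynamically
    consistent growth-elasticity continuum. The deformation gradient is
    decomposed multiplicatively into growth and elastic parts; a compressible
    neo-Hookean energy (or its incompressible limit) supplies the stress, a
    moving-boundary reaction-diffusion equation supplies the nutrient field,
    and the volumetric growth rate follows from an energy-dissipative
    chemomechanical feedback law. Includes radially-symmetric compressible and
    incompressible time-stepping solvers on a rescaled grid, an equilibrium
    shooting method with a load-existence threshold, Maxwell-limit and
    thermodynamic audits, a grid-search fitting toolkit with AICc model
    comparison, and a synthetic radius-series generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
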