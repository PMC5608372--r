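Package: embryOx
Title: Oxygen Transport Modelling and Migration Kinetics for Drosophila
    Embryos in Microfluidic Oxygen Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models oxygen supply to Drosophila embryos cultured in a
    microfluidic oxygen-gradient device and quantifies the developmental
    delays that hypoxia induces. Provides Stern-Volmer calibration of
    optical oxygen sensors, a parametric model of the device oxygen field,
    a three-dimensional finite-volume solver for steady-state and transient
    oxygen diffusion with zero-order cellular consumption and
    membrane-permeability (Robin) boundary exchange including dead-core
    handling, inverse estimation of the trans-embryonic oxygen permeability
    from migration-time equivalence constraints with sensitivity analysis,
    a one-term exponential dose-response model linking environmental oxygen
    to engrailed stripe migration time with right-censored observations,
    quantifiers for pole-cell and stripe migration kinetics, and a
    synthetic-data generator that emulates every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
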