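Package: pmfield
Title: Thylakoid Proton Motive Force Partitioning, Electrochromic Shift
    Analysis and Field-Dependent Photosystem II Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the thylakoid proton motive force (pmf)
    and its consequences for photosystem II (PSII) photodamage. Includes
    dark-interval relaxation kinetics (DIRK) analysis of the electrochromic
    shift (ECS) with three-wavelength deconvolution, partitioning of the
    light-induced pmf into its electric-field (delta-psi) and pH-gradient
    (delta-pH) components, pulse-amplitude-modulated (PAM) chlorophyll
    fluorescence quenching parameters (Fv/Fm, PhiII, LEF, qE, qI, qL),
    an ECS-to-millivolt calibration chain, a delta-psi-dependent
    S2QA- charge-recombination rate model, and a deterministic kinetic
    simulator of the PSII back-reaction scheme with singlet-oxygen yields.
    A seeded synthetic-data generator produces light schedules and ECS,
    fluorescence, photoinhibition and flash traces with known ground
    truth, so every estimator can be validated by round-trip recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite
Config/testthat/edition: 3
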