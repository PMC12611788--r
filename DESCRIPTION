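Package: cardionuc
Title: Sarcomere-Nuclear Strain Coupling, Cytoskeletal Pre-Stress Modelling
    and Nuclear Damage Quantification in Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for cardiomyocyte nuclear mechanobiology.
    Implements a sarcomere-nuclear strain-coupling assay (beat averaging,
    strain normalization, systolic and diastolic dampening areas, integrated
    nuclear strain), an axisymmetric chemo-mechanical finite-element model of
    the resting cardiomyocyte (active myofibril contractility with
    chemo-mechanical feedback, a compressive perinuclear microtubule cage, and
    a nucleus split into nearly incompressible chromatin and an incompressible
    envelope-plus-lamina layer) predicting nuclear shape and envelope stress,
    microscopy quantification of perinuclear enrichment and nuclear-damage
    foci, continuity-constrained piecewise (biphasic) regression with
    deflection-point detection, and seeded synthetic-data generators with
    ground truth for every pipeline input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
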