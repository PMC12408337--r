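Package: isfac
Title: Partial Atomic Charges from Electron Diffraction by Ionic Scattering Factor Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Crystallographic least-squares refinement against 3D electron
    diffraction intensities in which every atom carries one extra refined
    parameter, the fraction of an ionic electron scattering factor, yielding
    experimental partial charges on an absolute scale. Includes generation of
    neutral and ionic electron scattering factors from the charge-offset
    Mott-Bethe formula with Cromer-Mann parametrization, kinematical structure
    factors, full-matrix refinement with restraints and uncertainty estimates,
    stability diagnostics (leave-one-out cross validation, resolution scans,
    multi-dataset merging), electrostatic potential map synthesis and grid
    comparison, readers and writers for SHELX-style reflection and instruction
    files, and a synthetic-data module that builds toy crystal structures with
    known ground-truth charges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
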