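Package: boronparam
Title: Amber Force-Field Parameterization for Boronates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to derive and validate Amber force-field parameters for
    boron-containing small molecules (boric acid esters, boronates).
    Implements Seminario-method extraction of harmonic bond and angle
    constants from a Cartesian Hessian, hybrid genetic-algorithm plus
    downhill-simplex fitting of truncated-Fourier dihedral terms to a
    QM-minus-MM torsion profile, reading and writing of Tripos mol2 and
    Amber frcmod files, evaluation and minimization of the Amber potential
    with analytic gradients, Kabsch-superposition RMSD validation metrics,
    and minimal thermostatted vacuum dynamics. A synthetic-data generator
    provides Hessians, torsion scans and perturbed reference structures so
    the whole pipeline is testable without external quantum-chemistry or
    crystallographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
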