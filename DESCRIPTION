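Package: furanoseFF
Title: Torsion and Charge Parameterization for Fluorinated Furanose Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive Amber-style force-field parameters for mono-,
    di- and gem-fluoro/hydroxy substituted furanose rings. Implements
    Altona-Sundaralingam pseudorotation mathematics (phase and amplitude
    from endocyclic torsions, Cartesian ring embedding at a target pucker),
    pseudorotation scans and randomized pose ensembles with RMSD culling,
    an additive molecular-mechanics energy with per-term decomposition,
    linear least-squares fitting of dihedral Fourier coefficients against
    reference energies with a 5 percent iterative convergence rule,
    electrostatic-potential charge fitting with implicit polarization
    (vacuum/solvated midpoint), and sugar-pucker trajectory analysis
    (percent North, phase histograms, per-window energy-error statistics,
    through-origin regression). A synthetic oracle generates self-consistent
    reference energies and ESP grids so every fitting stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
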