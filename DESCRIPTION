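Package: nucgeom
Title: Rigid-Body Step Geometry and Conformational Analysis of Nucleic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conformational analysis of single- and double-stranded DNA
    oligomers: least-squares base reference frames, the six base-step
    rigid-body coordinates (shift, slide, rise, tilt, roll, twist) and the
    helical rise/twist via a mid-frame (CEHS-style) algorithm, furanose
    pseudorotation and pucker classification, backbone torsions, geometric
    base-stacking and inter-base hydrogen-bond detection with per-trajectory
    statistics, end-to-end distances, RMSD after optimal superposition, and
    slide-roll A/B-form classification.  Includes a fiber-model structure
    generator that builds ideal A- and B-form single strands and duplexes
    from published fiber-diffraction step parameters, controlled rigid-body
    perturbations of them, and mock multi-snapshot trajectories with
    programmed stacking probabilities and hydrogen-bond event rates for
    validating the detectors against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
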