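Package: mrelastic
Title: Magnetic Resonance Elastography Reconstruction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of complex shear modulus maps from magnetic
    resonance elastography (MRE) phase-image series: phase-difference
    computation from sign-alternated motion-encoding acquisitions,
    least-squares 2D phase unwrapping, temporal harmonic extraction,
    Butterworth band-pass and directional wave filtering, and 2D Helmholtz
    inversion yielding storage modulus, loss modulus, magnitude modulus and
    phase angle with regional summaries. Includes a plane-wave forward
    simulator with known ground-truth viscoelasticity, saturation-recovery
    T1 mapping (delta-T1 and percent signal-intensity change), relative
    gene-expression quantification by the 2^-ddCt method, and the
    correlation analyses (Spearman with exact small-sample permutation
    p-values, Pearson) used to relate tissue stiffness to clinical score
    and expression data in neuroinflammation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
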