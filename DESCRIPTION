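Package: immunoCID
Title: Gas-Phase Immune-Complex Dissociation Analysis and Binding-Strength Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of native nano-electrospray mass spectrometry breakdown
    experiments on intact antibody-peptide immune complexes. Processes
    per-collision-voltage spectra (scan averaging, iterated Savitzky-Golay
    smoothing, charge-state envelope Gaussian fitting with imputation,
    zero-charge mass deconvolution), computes normalized educt dissociation
    courses, fits Boltzmann sigmoids, applies a four-criterion quality gate,
    derives apparent gas-phase kinetic and thermodynamic values via
    Eyring-Polanyi, Arrhenius, Gibbs-Helmholtz and van't Hoff relations, and
    ranks wild-type against single-amino-acid-polymorphism epitope peptides.
    Includes a synthetic spectrum/titration generator with known ground truth
    and an independent single-site (Wiseman) isothermal titration calorimetry
    model fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mzR,
    optparse
Config/testthat/edition: 3
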