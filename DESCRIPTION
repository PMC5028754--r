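Package: picsitc
Title: Protease Substrate-Specificity Profiling (PICS) and ITC Binding Isotherm Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two bespoke biophysical analyses. First, a Proteomic
    Identification of protease Cleavage Sites (PICS) pipeline: filtering of
    peptide-identification lists from a protease-treated proteome-derived
    peptide library (biotinylated neo-N-terminus filter, confidence thresholds,
    mock/inactive-control subtraction, unprocessed-library removal), exact
    back-mapping of surviving prime-side peptides to a proteome to reconstruct
    P5-P1 non-prime residues, and construction of the 20 x 10 (P5-P5')
    substrate-specificity matrix. Second, isothermal titration calorimetry
    (ITC) analysis: forward simulation of injection heats under single-site and
    two-independent-sites binding models with perfusion-cell displacement
    corrections, least-squares fitting of both models, chi-square profiling of
    the two dissociation constants, and conversion of affinities to free
    energies. A synthetic-data module generates proteomes, tryptic peptide
    libraries, protease digests with identification noise, and simulated
    titrations so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
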