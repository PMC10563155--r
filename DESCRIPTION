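Package: acetylAPMS
Title: Two-Step Digestion and Label-Free Quantification for AP-MS with
    Acetylated Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for affinity-purification mass spectrometry (AP-MS)
    workflows in which the bead-bound ligand (e.g. an anti-GFP nanobody or
    streptavidin) is chemically acetylated on its lysines to block Lys-C and
    trypsin cleavage. Provides a modification-aware in-silico protease
    digestion engine (cleavage-site finding, missed-cleavage enumeration,
    two-step on-bead Lys-C then in-solution trypsin digestion, stochastic
    lysine acetylation, released-ligand-signal prediction, monoisotopic mass
    utilities), a label-free quantification post-processing pipeline
    (protein filtering, pairwise ratio-mode normalization,
    downshifted-Gaussian imputation of left-censored missing values,
    replicate-pair ratios, coefficients of variation, quantified-protein
    counts, ligand-contamination reporting), a synthetic AP-MS experiment
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
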