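Package: prsda
Title: Template-Based Protein Backbone Reconstruction with a Stacked
    Denoising Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs protein backbone structures from homologous
    template structures using a per-target stacked denoising autoencoder.
    Decoy ensembles with a controlled RMSD spread are generated from each
    template by torsion-space perturbation, encoded as flat per-residue
    coordinate features in a normalized unit box, and used to train a
    tied-weight autoencoder whose labels are the template native
    coordinates.  The trained model maps a crude input conformation (an
    extended chain by default) to a refined backbone model written as a
    standard PDB file.  Includes backbone PDB input/output, Kabsch
    superposition, RMSD and GDT/GDT-TS scoring, an internal-to-Cartesian
    chain builder, a synthetic native/decoy generator for fully
    self-contained experiments, and evaluation utilities (threshold
    counts, paired t-tests) over benchmark result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
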