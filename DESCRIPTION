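Package: altconf
Title: Sampling and Analysis of Alternative Protein Conformations from
    Subsampled-MSA Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for driving a protein structure-prediction network to
    sample alternative conformations by seeded stochastic subsampling of
    multiple sequence alignments, and for analysing the resulting model
    ensembles. Provides A3M/FASTA alignment handling with depth subsampling,
    run-specification manifests encoding a reduced-recycling prediction
    protocol, Calpha structure handling with terminal truncation and
    sequence-based residue correspondence, Kabsch superposition, TM-score
    with the standard length-dependent d0, ensemble alignment, per-residue
    displacement and RMSF profiles with confidence filtering, misfolded-model
    exclusion by coclustering, principal component analysis of Calpha
    coordinates with extreme-model selection, and a synthetic two-state
    fixture generator so every analysis stage is testable without GPU
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
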