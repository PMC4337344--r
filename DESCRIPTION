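Package: ecmcycle
Title: Eigenvector Centrality Mapping of Longitudinal Resting-State fMRI
    Across the Menstrual Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A longitudinal resting-state fMRI analysis pipeline linking
    menstrual-cycle hormone levels to whole-brain functional connectivity.
    Implements fast eigenvector centrality mapping of voxel-wise BOLD
    correlation networks (matrix-free power iteration on the shifted Pearson
    similarity matrix), Gaussian spatial smoothing, gray-matter mask
    construction, voxel-wise general linear models with hormone covariates,
    cluster-extent thresholding with family-wise error correction over
    resolution elements, and seed-based Fisher-z connectivity analysis.
    A synthetic-study generator produces hormone panels with realistic
    menstrual-cycle dynamics and 4D BOLD-like volumes with known,
    progesterone-modulated coupling, so every pipeline stage is testable
    end to end without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
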