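Package: poseval
Title: Evaluation Toolkit for Protein-Ligand Docking and Co-Folding Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores predicted protein-ligand complex structures against
    reference (crystal) structures without requiring any external predictor.
    Implements symmetry-corrected heavy-atom ligand RMSD, centroid RMSD,
    lDDT and its protein-ligand-interface variant (lDDT-PLI), geometric
    detection of protein-ligand interaction fingerprints (PLIFs), the
    Wasserstein-based PLIF-EMD and PLIF-WM metrics, PoseBusters-style pose
    validity checks with steric-clash counting, binding-pocket definition and
    pocket-focused apo-to-holo superposition with optimal chain mapping, and
    primary- and multi-ligand evaluation protocols with success-rate
    aggregation across runs. Ships a deterministic synthetic-complex
    generator with planted, closed-form ground-truth metric values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    clue,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
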