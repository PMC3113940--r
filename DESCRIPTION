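Package: stabscan
Title: Structure-Based Prediction of Protein Stability Changes upon Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives knowledge-based statistical potentials from protein
    structures and combines them, with solvent-accessibility-dependent
    sigmoid weights and amino-acid volume terms, into a predictor of the
    folding free-energy change (ddG) caused by single-site point mutations.
    Includes tools to train and cross-validate the combination against
    measured mutant datasets, to run in-silico saturation mutagenesis
    scans, and to compute per-position sequence-optimality scores that
    flag structural weaknesses. A synthetic fixture generator produces
    toy structures and simulated mutant datasets with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
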