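Package: trajpka
Title: Tracking pKa Values of Ionizable Residues Along Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iteratively predicts per-frame pKa values of ionizable
    residues over molecular dynamics ensembles with a pluggable
    per-structure engine (an external empirical predictor or a built-in
    deterministic engine), and analyses the resulting time series:
    alanine pseudo-mutation scanning, running-average time evolutions,
    pKa distributions, protonation-sensitivity flagging, correlation
    scanning against user-supplied collective-motion projections,
    conformational clustering with silhouette-optimised hyperparameters,
    and mapping of per-residue values onto 3D structures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
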