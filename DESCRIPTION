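Package: confatlas
Title: Conformational Ensemble Atlases for GTPase Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds principal-component "atlases" from crystallographic
    ensembles of protein structures and projects trajectory conformers into
    them to classify conformational states, with Ras GTPases as the motivating
    system. Implements iterated-superposition search for the structurally
    invariant core of an ensemble, Kabsch least-squares superposition and RMSD,
    covariance PCA of C-alpha coordinates with hierarchical state clustering,
    and per-trajectory analytics: replicate-averaged RMSF with paired t-tests,
    dynamic cross-correlation maps, catalytic atom-pair distance series, and
    pseudo C-alpha torsion difference profiles. A synthetic-data module
    generates ensembles and trajectories with planted modes, clusters, rigid
    cores and correlation structure so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
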