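Package: icdc
Title: Integrated Co-Evolution and Dynamic Coupling Analysis of Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies distal residue positions that modulate protein
    function by combining coarse-grained dynamics with sequence
    co-evolution. Builds anisotropic elastic-network Hessians from PDB
    structures (or ingests molecular-dynamics covariance matrices),
    performs perturbation response scanning to obtain per-residue dynamic
    flexibility (DFI) and dynamic coupling (DCI) profiles, scores
    column-pair co-evolution in multiple sequence alignments with
    sequence-weighted mutual information and average-product correction,
    and bins positions into four binary categories by rigidity, coupling
    to a functional site, and co-evolution with that site. Also proposes
    alignment-supported substitutions at candidate positions, stratifies
    deep-mutational-scanning fitness tables by category, and maps
    hydrogen-bond pathways between residues across structural ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
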