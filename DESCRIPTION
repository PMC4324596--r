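Package: cdnet
Title: Coupled-Dynamics Networks from Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds residue-residue coupled-dynamics networks from
    conformational ensembles (multi-model PDB trajectories). Computes
    per-residue root mean square fluctuations, dynamic cross-correlation
    maps, and contact frequencies; constructs correlation-weighted residue
    graphs; selects the critical correlation cutoff at which the largest
    connected component comprises a target fraction of residues; identifies
    bottleneck ("critical node") residues whose removal disconnects the
    network into sizeable components; and computes optimal coupling paths
    between distant sites with Dijkstra's algorithm on contact-filtered
    graphs with edge weights 1 - |C_ij|. Includes a Gaussian factor-model
    generator of synthetic ensembles with planted community and bottleneck
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
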