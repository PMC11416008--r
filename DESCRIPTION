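Package: GeoPocket
Title: Ligand-Agnostic Protein Binding Site Prediction with Geometric
    Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Residue-level prediction of small-molecule binding sites on
    protein structures without knowledge of the ligand. Candidate pocket
    centers (e.g. from Fpocket) are scored for druggability by a
    binding-site detection (BSD) model and refined to binding-residue sets
    by a binding-residue identification (BRI) model. Both models share an
    SE(3)-invariant trunk: a per-residue 3D convolutional feature
    extractor over local-frame voxel grids followed by geometric
    self-attention over residue frames. The package also implements
    inter-resolution transfer learning between the two tasks, a
    homology-based label-augmentation scheme that transfers binding-site
    evidence across aligned chains, the detection/segmentation evaluation
    metrics (DCA success rate, average and conditional IOU), and a
    synthetic-complex generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
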