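Package: fovex
Title: Field-of-View Expansion for Multi-Camera Endoscopic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline construction of expanded endoscopic views from multiple
    cameras localized by visual SLAM. Implements closed-form absolute
    orientation (Horn's quaternion method) for similarity-transform
    estimation between corresponding 3D map points, a robust variant based
    on median-centred quaternion filtering over all three-point
    combinations, inlier-maximizing triple search, automatic key-frame pair
    selection, the projection geometry of three view-presentation methods
    (single-plane, overlap removal, cylindrical approximation), a software
    compositor, image-similarity metrics (zero-mean normalized
    cross-correlation and mutual information), and a seeded synthetic
    benchmark for parameter-recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
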