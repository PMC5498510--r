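Package: tractparc
Title: Cortex-Associated Individual White-Matter Parcellation from
    Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parcellates the whole white matter of an individual subject
    into cortex-region-associated areas by combining a cortical
    parcellation with deterministic streamline tractography. Streamlines
    are seeded in (or assigned to) cortical regions, labeled by their
    region of origin, and accumulated into a per-voxel candidate image of
    label counts; every white-matter voxel is then classified by a
    weighted vote combining its own label distribution with the
    inverse-distance-weighted distributions of its 26 neighbors. Includes
    a minimal deterministic FACT (fiber assignment by continuous
    tracking) tracker, TrackVis and NIfTI input/output, a nearest-cortex
    baseline parcellation, majority-vote group averaging, Dice overlap
    scoring, and a seeded synthetic phantom generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
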