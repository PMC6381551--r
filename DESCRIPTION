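Package: nodtex
Title: Scan-Parameter Effects on CT Radiomic Texture Features in
    Simulated Lung-Nodule Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates CT-like volumes of spherical lung-nodule phantoms
    (solid +100 HU and ground-glass -630 HU) under a 3x2x2 factorial of
    slice thickness (1.25, 2.5, 5.0 mm), tube current (30, 120 mAs) and
    reconstruction kernel (lung, standard), with ten repeat scans per
    condition and nodule relocation. Segments nodules by seeded region
    growing, extracts twenty three-dimensional radiomic features (seven
    histogram features plus gray-level co-occurrence and run-length
    texture features over thirteen directions at distance one), and
    quantifies the effect of each scan parameter with dummy-coded
    multiple regression, absolute regression-coefficient summaries and
    Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
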