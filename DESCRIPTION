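Package: leukoseg
Title: Quick Leukocyte Nucleus Segmentation by B-G Channel Differencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fast segmentation, localization and counting of white-blood-cell
    nuclei in Wright-Giemsa stained peripheral blood smear micrographs. Nuclei
    are segmented by thresholding the saturated blue-minus-green (B-G) channel
    difference with a fixed empirical threshold, platelets are removed by
    size filtering, multilobed (e.g. neutrophil) nuclei are regrouped by an
    area-capped centroid-distance rule, and each nucleus is localized by
    projection-profile bounding boxes. Nucleus-colored cytoplasm-free
    artifacts are rejected by a cytoplasm-to-nucleus area-ratio rule backed
    by an Otsu-based saturation/blue cytoplasm segmentation. Includes an
    Otsu-on-S-and-B baseline segmenter, a synthetic stained-smear generator
    with per-object ground truth, detection scoring, differential-count
    reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jpeg,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
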