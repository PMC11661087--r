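Package: axoncaliber
Title: Axon Caliber Quantification from Membrane-Labeled Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Line-scan measurement of axon caliber from membrane-labeled
    fluorescence microscopy images, with a synthetic scene generator that
    provides exact ground truth. Caliber is scored as the distance between
    the two plasma-membrane intensity peaks along a profile perpendicular
    to the axon centerline. Downstream analyses cover branch-point symmetry
    and taper scaling, caliber dynamicity over time-lapse series (%RSD),
    pearling (lengthwise caliber SD), and the geometry of axons crossing
    dividing basal epithelial cells (round/flat frame selection, paired
    comparisons, and a circular-arc path-length model). Paired permutation
    and rank-sum tests are implemented with exact small-sample enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
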