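Package: pawSSI
Title: Automated Static Sciatic Index from Under-Box Rodent Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Batch pipeline that computes the static sciatic index (SSI)
    from videos of rats filmed from below a transparent box. Frames are
    cropped to a user-defined region of interest, hind-paw digits are
    segmented and labelled, toe spread (TS) and intermediate toe spread
    (ITS) are measured for the operated and control paws, and per-frame
    SSI values are computed, filtered for outliers and aggregated per
    video. Includes a parameterised synthetic-scene renderer with exact
    ground truth so every stage can be verified without animal data, and
    exports per-video measurement tables as XLSX and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xml2
biocViews: Software, Segmentation, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
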