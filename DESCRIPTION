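Package: fuzzyweed
Title: Monocot and Dicot Weed Discrimination from Field Images Using
    Shape Descriptors and Fuzzy Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminates grass-type (monocot) from broad-leaved (dicot)
    weed seedlings in inter-row RGB field images. Vegetation is segmented
    with a linear greenness colour index and a morphological opening,
    connected regions are labelled by a run-length algorithm, and each
    region is characterised by the seven Hu invariant moments plus six
    geometric shape descriptors. Regions are classified by one of four
    decision-making engines trained from per-attribute error rates: the
    Choquet fuzzy integral, the Sugeno fuzzy integral, Dempster-Shafer
    evidence combination, and fuzzy multicriteria decision making (fuzzy
    TOPSIS). A seeded synthetic field-image generator emulating the target
    imagery makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
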