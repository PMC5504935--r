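Package: spellerseg
Title: P300 Speller-Driven Fuzzy Color Object Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Illumination-robust seeded color segmentation driven by a
    P300 brain-computer interface. Implements a fuzzy color extractor
    whose similarity pattern is the angle between pixel vectors in RGB
    space, with Mamdani fuzzification, centroid defuzzification, seeded
    subregion growing, largest-subregion object selection and row/column
    gap filling; plus a 3x3 P300 speller pipeline (stimulus scheduling,
    band-pass preprocessing, epoch feature extraction, shrinkage Fisher
    linear discriminant classification and online voting) that selects
    which object's seed pixel and fuzzy parameters are fed to the
    extractor. Includes synthetic scene and EEG session generators for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
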