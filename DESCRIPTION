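Package: dermatex
Title: Texture and Lesion-Area Based Recognition of Common Skin Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage image-analysis pipeline for recognising three
    common skin conditions (herpes, paederus dermatitis, psoriasis) from
    2-D colour skin images. Images are denoised with a median filter,
    rotated so the epithelium's long axis is horizontal, and divided into
    ten vertical regions along the medial axis of the Euclidean distance
    transform. Gray-level co-occurrence matrix (GLCM) statistics
    (contrast, correlation, entropy, uniformity, energy) are extracted
    per region, the lesion area is quantified by marker-controlled
    watershed segmentation with k-means region merging and morphological
    cleanup, and the combined texture + area feature vector is classified
    with one-vs-one soft-margin support vector machines using a radial
    basis function kernel. A synthetic-image generator with known ground
    truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
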