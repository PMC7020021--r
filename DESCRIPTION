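Package: cheekmorph
Title: Region-Based 3D Volumetric Analysis of Midface Soft-Tissue Response
    to Le Fort I Maxillary Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the anteromedial cheek soft-tissue response
    to Le Fort I maxillary advancement and clockwise (pitch) rotation from
    pre- and post-operative 3D surface models. Implements landmark-based
    construction of the craniofacial reference frame and planes (Frankfort
    horizontal, midsagittal, occlusal, cheek-bounding planes), rigid
    best-fit superimposition over non-operated regions with an RMS accuracy
    gate, plane-bounded region-of-interest clipping, volumetric subtraction
    (average sagittal movement as volume change divided by pre-operative
    surface area), the cheek-mass position metric against the cornea
    perpendicular plane, and the cohort statistics used to predict soft-
    from hard-tissue movement (zero-intercept multiple regression with
    partial R-squared, soft-to-bone movement ratios, stratified normative
    comparisons, ICC, Kolmogorov-Smirnov normality). A parametric
    craniofacial phantom generator produces bone/soft surface pairs with
    known surgical movements so the whole pipeline can be exercised and
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
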