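Package: stemstate
Title: Label-Free Assessment of Mesenchymal Stem Cell Differentiation
    State from FLIM and SRS Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the differentiation status of mesenchymal
    stem cells (MSCs) from label-free microscopy. Implements bi-exponential
    fitting of NAD(P)H fluorescence decays to obtain the protein-bound
    fraction a2, sliding-window single-cell segmentation of dense adherent
    monolayers, extraction of metabolic (a2 histogram peak and FWHM) and
    morphological/lipid (area, perimeter, circularity, mean SRS intensity)
    features, and unsupervised K-means++ clustering with elbow-rule model
    selection to classify cells as undifferentiated, differentiating or
    differentiated. A synthetic-data generator renders FLIM a2 maps and SRS
    lipid images with per-cell ground truth so the whole pipeline can be
    exercised and benchmarked without access to microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
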