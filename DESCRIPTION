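Package: anascreen
Title: Automated Antinuclear Antibody Screening on HEp-2 Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative screening of antinuclear antibodies (ANA) from paired
    DAPI/FITC indirect-immunofluorescence captures of HEp-2 cells. Nuclei are
    segmented from the DAPI channel by histogram background-peak detection and
    twice-background thresholding; the segmentation is superimposed on the FITC
    channel to form a fluorescence index (FI), the ratio of mean nuclear to mean
    background fluorescence, which is classified against a calibratable cutoff.
    Includes the evaluation battery used to validate such screeners
    (sensitivity, specificity, predictive values, accuracy, Cohen's kappa,
    ROC/AUC, accuracy-curve cutoff determination, Mann-Whitney U, Spearman rank
    correlation, coefficient of variation) and a synthetic HEp-2 capture
    generator with known ground truth for end-to-end testing without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
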