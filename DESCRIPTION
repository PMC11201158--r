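Package: ildquant
Title: Pixel-Wise Quantification of Interstitial Lung Disease Extent on
    Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised quantification of interstitial lung disease
    (ILD) on chest radiographs. Segments the lung fields with a U-Net,
    synthesizes a lesion-free "virtual normal" counterpart of a diseased
    radiograph by contrastive unpaired image-to-image translation, scores
    disease extent as the fraction of lung-field pixels left hyperintense
    after subtracting the virtual normal, and classifies longitudinal
    interval change (aggravation / no change / improvement) from the
    extent-score delta. Ships a seeded synthetic phantom-radiograph
    generator with exact ground-truth lung and lesion masks so the whole
    pipeline is exercisable and testable on CPU, plus Dice/SSIM/PSNR and
    one-vs-rest classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
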