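Package: noise2fast
Title: Blind Zero-Shot Single-Image Denoising via Chequerboard Downsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Denoises a single noisy 2D image with no external training data,
    no clean reference and no noise model. The image is split into four
    chequerboard-downsampled half-images; a small fully convolutional network
    is trained to map each downsample to its parity complement (a
    Noise2Noise-style objective), while the original noisy image serves as a
    validation set, so training stops at the checkpoint where the network
    output on the noisy image most resembles the image itself. Includes
    TIFF/PNG input/output for 8/16-bit integer and 32-bit float microscopy
    images, reference PSNR/SSIM metrics, a synthetic phantom and noise
    generator for fully self-contained testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
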