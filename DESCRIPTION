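Package: rlre
Title: Weighted Low-Rank Matrix Restoration for MR Image Denoising
Version: 0.1.0
Authors@R:
    person("rlre", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Denoises grayscale magnetic resonance images by decomposing the
    pixel matrix D into a low-rank background H, a sparse component S and a
    dense Gaussian-noise term E (D = H + S + E), minimising a weighted
    nuclear norm on H plus a weighted L1 penalty on S plus a Frobenius
    penalty on E via an inexact augmented-Lagrangian scheme with one-step
    reweighting.  Includes the unweighted robust-PCA baseline, global PSNR
    and SSIM image-quality metrics, seeded synthetic phantoms and a
    benchmark harness, diagnostic-accuracy statistics for 2x2 contingency
    tables (sensitivity, specificity, accuracy, Cohen's kappa, Pearson
    chi-square), plain-text image I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
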