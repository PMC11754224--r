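Package: pcdenoise
Title: Unsupervised LiDAR Point-Cloud Denoising by Noise Doubling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised denoising of LiDAR point clouds for individual-tree
    extraction. A displacement-predicting network is trained on noisy clouds
    alone: injecting a second, independent noise realization into an already
    noisy cloud yields a regression target equal to twice the single-noise
    displacement, so no clean reference is ever needed. The package ships the
    full training loop (k-NN graph features, global pooling, MLP displacement
    head with residual output, cosine-annealed Adam), the displacement MSE plus
    repulsion objective, classical Statistical and Radius Outlier Removal
    baselines, point-cloud quality metrics (MSE, SNR, one-way Hausdorff,
    neighborhood-based 3D SSIM), readers and writers for LAS, PLY and XYZ
    point-cloud formats, and a synthetic forest-scene generator with analytic
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
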