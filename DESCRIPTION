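Package: fedpet
Title: Federated Deep Learning for PET Attenuation and Scatter Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for multi-centre, privacy-preserving
    training of image-domain attenuation/scatter correction (AC/SC) models for PET.
    Provides a 2D multi-centre phantom simulator with heterogeneous scanner profiles
    (resolution blur, pseudo-Poisson noise, scatter fraction, matrix size), SUV
    conversion and intensity-normalisation preprocessing, a nested residual U-block
    network (U2-Net style) with deep supervision implemented from first principles,
    four training strategies (centre-based, centralized, parallel federated with
    FedAvg-style weighted aggregation, and sequential federated weight transfer),
    voxel-wise image-quality metrics (ME, MAE, RE%, ARE%, PSNR, SSIM), joint-histogram
    analysis, and a Mann-Whitney / Benjamini-Hochberg comparison protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
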