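Package: parsstain
Title: Multi-Channel Virtual Histological Staining for Photon Absorption
    Remote Sensing Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for turning time-resolved non-radiative photon absorption
    remote sensing (PARS) signals into virtual hematoxylin-and-eosin images.
    Provides extraction of the conventional PARS channels (non-radiative
    integrals per excitation wavelength, radiative amplitude, scattering
    baseline), a scale- and sign-invariant angular K-means feature learner
    with pseudo-inverse spectral unmixing, a multi-channel cycleGAN
    (UNet generators, PatchGAN discriminators) that accepts arbitrary
    channel subsets and emits RGB output, image-quality metrics with
    pre-metric Gaussian blurring (SSIM, PSNR, RMSE), cluster-count and
    channel-combination selection studies, and a synthetic tissue phantom
    generator so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
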