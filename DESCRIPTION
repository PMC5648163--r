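Package: enamelwave
Title: Dynamic Models of Tooth Enamel Mineralization from Ontogenetic Density Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts a cross-sectional (ontogenetic) series of virtual enamel
    density sections into a dynamic, probabilistic model of tooth
    mineralization. Provides linear grey-to-density calibration for
    synchrotron-style scans, standardization of tooth shape into
    enamel-dentin-junction (EDJ) coordinates, integrated-Gaussian
    (error-function) growth-curve fitting with size-modeled age
    re-assignment, per-pixel Metropolis-Hastings sampling of monotone
    mineralization trajectories under a Gaussian likelihood with a flat
    prior, assembly of posteriors into an HDF5 model
    (age_mask/ages/locations/pct_min_samples), and derived products:
    daily-interpolated trajectories, mineralization-rate fields, and
    time-averaging maps. A forward simulator of two-wave enamel growth
    generates synthetic sections with known ground truth so every stage is
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    rhdf5,
    tiff,
    png,
    EBImage,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
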