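Package: opfit
Title: Orthogonal Polynomial Fitting of Scattered Air-Pollutant Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial interpolation of scattered pollutant observations
    (e.g. city-level PM2.5 concentrations) by least-squares surface fitting
    in a tensor-product Chebyshev polynomial basis, together with two
    classical comparators: Cressman objective analysis with an adaptive
    influence radius and ordinary kriging with a fixed spherical
    semivariogram. Includes an evaluation toolkit (MAE/RMSE, absolute-error
    binning, spatially stratified k-fold hold-out cross-validation, and a
    polynomial order search) and a twin-experiment simulator that generates
    bimodal truth fields and synthetic station networks, so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
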