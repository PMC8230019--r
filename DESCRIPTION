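Package: olivephen
Title: Developmental-Rate Phenology Modelling for Olive
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Thermal-time phenology modelling for olive (Olea europaea)
    based on developmental-rate (DR) functions of mean air temperature and,
    optionally, daylength. Provides linear, multiple-linear and
    second-degree polynomial DR response functions with base-temperature
    and cardinal-threshold derivation, a daily summing-rates simulator that
    predicts phase lengths and end dates from daily weather, a reverse
    simulation mode that reconstructs budbreak dates from observed
    flowering dates, ordinary-least-squares calibration of DR functions
    from BBCH-coded phenological observations, repeated K-fold
    cross-validation with r2/RMSE/MBE reporting, bundled final calibrations
    for the six cross-validated budbreak/inflorescence-to-flowering phases,
    and a synthetic-data generator emulating a multi-site Italian
    phenological survey for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
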