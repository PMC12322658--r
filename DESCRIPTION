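Package: optodose
Title: Hybrid Kinetic Modeling of Light-Inducible Protein Production in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling optogenetic protein production in Komagataella
    phaffii (Pichia pastoris) batch cultures. A Monod-type system of ordinary
    differential equations describes growth, substrate consumption and
    light-induced intracellular protein expression; its kinetic parameters are
    treated as functions of blue-light intensity and EL222 transcription-factor
    copy number, learned per condition by particle-swarm parameter estimation
    and interpolated across conditions with Matern-5/2 Gaussian-process
    surrogates. Includes plate-reader fluorescence normalization, photon-flux
    to irradiance conversion, a synthetic-data generator with a
    copy-number-dependent phototoxicity structure, dose-landscape scanning to
    locate the production-maximizing light intensity per strain, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
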