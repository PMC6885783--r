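Package: ppeshield
Title: Photon Attenuation and Aerosol-Immersion Dosimetry for Radiation-Protective Clothing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises the shielding performance of personal protective
    equipment (PPE) with heavy-metal shielding layers.  Provides bundled
    elemental photon cross-section tables with mixture-rule mass attenuation
    coefficients, narrow-beam Beer-Lambert analytics and lead equivalents;
    gamma-spectrometry peak-area analysis turning paired open-beam/sample
    spectra into relative penetration, measured mass attenuation coefficients
    and mean lead equivalents with uncertainty propagation; a seeded Monte
    Carlo photon transport engine (Klein-Nishina sampling, kerma
    approximation) for slab penetration and for a radon-aerosol test chamber
    holding a stylized anthropomorphic phantom; ICRP 103 effective-dose
    assembly for dispersed radioactive aerosols with an empirical
    beta-transmission model; and a synthetic spectrum generator emulating
    point-source acquisitions with detector resolution and Poisson noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
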