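Package: wgmsense
Title: Whispering-Gallery-Mode Sensing of Intracellular Lipid Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whispering-gallery-mode (WGM) resonance
    spectra emitted by dye-stained lipid droplets inside live adipocytes.
    Fits resonance spectra with a Lorentzian superposition at high
    signal-to-noise ratio or with empirical sinusoid models at low
    signal-to-noise ratio, estimates absolute droplet diameter from the
    free spectral range and from first-order radial mode assignment,
    tracks nanometer-scale diameter changes over time, inverts TE/TM
    mode splitting to the cytoplasm refractive index, converts diameter
    kinetics into lipolytic flux metrics, and flags cell-viability
    transitions. Includes a physically grounded synthetic-spectrum
    generator with known ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
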