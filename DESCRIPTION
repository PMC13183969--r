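Package: fnirstwin
Title: Digital Twin of an sCMOS-Based Continuous-Wave fNIRS Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a scientific-CMOS camera based continuous-wave
    functional near-infrared spectroscopy (fNIRS) instrument and its
    computational chain: dual-wavelength time-division-multiplexed optode
    arrays, speckle-spot frame rendering with a Poisson/Gaussian photon
    transfer noise model, region-of-interest extraction to per-channel mean
    grayscale value (MGV) time series, tissue-mimicking phantom forward
    models (Intralipid/India-ink titration, blood-doped deoxygenation,
    block-design hemodynamics, drift streams), instrument characterization
    metrics (two-state SNR, noise-equivalent power, dynamic optical range,
    Allan deviation, drift rate), and the preprocessing plus modified
    Beer-Lambert law pipeline recovering hemoglobin concentration and
    oxygen-saturation changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
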