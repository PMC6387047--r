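Package: fogdetect
Title: Wavelet-Energy Detection of Freezing of Gait from Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects freezing-of-gait (FOG) episodes in tri-axial accelerometer
    recordings from the lower limb. The magnitude of acceleration is analysed in
    sliding 256-sample windows with a five-level orthonormal Haar discrete
    wavelet transform; the percentage of total window energy held by the
    first-level detail coefficients (the 2-4 Hz band at 8 Hz sampling) drives a
    2 percent threshold rule that switches a vibratory-cueing stimulation state
    on and off once per second. Includes a labelled synthetic gait-signal
    generator, streaming and batch detectors, episode-level
    sensitivity/specificity/effectiveness metrics, and a command-line interface
    for simulation, detection and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
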