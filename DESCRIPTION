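Package: ventfeedback
Title: Simulation and Analysis of a Real-Time Bag-Valve Ventilation Feedback Device
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Software emulation of a real-time ventilation feedback device for
    bag-valve ventilation, together with its bench-validation protocol and the
    statistical analysis of a randomised crossover manikin trial. Provides
    synthetic flow/pressure waveform generators (volume-controlled ventilator
    cycles and operator-variable bag squeezes), the device signal chain (40 Hz
    sampling, 10-bit quantisation, flow-sensor voltage transfer, 1.75 s
    tidal-volume accumulation, breath onset detection, interval timing and
    bagging alarms), adequacy classification of tidal volume and ventilation
    interval, difference-ratio validation with tolerance bands, and marginal
    logistic (generalised estimating equation) models with exchangeable
    working correlation and robust variance for clustered binary outcomes,
    plus a McNemar paired-proportions sample-size calculator and a whole-trial
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
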