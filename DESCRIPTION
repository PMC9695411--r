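Package: pnhmicro
Title: Microelectrode LFP and Single-Unit Analysis of Periventricular Nodular Heterotopia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for interictal epileptic patterns and single-unit
    firing recorded with hybrid macro-microelectrodes in periventricular nodular
    heterotopia (PNH). Provides a synthetic-recording generator with known ground
    truth (1/f background LFP, periodic and sporadic discharges and epileptic
    spikes with superimposed narrow-band 60-200 Hz fast activity, gain-modulated
    inhomogeneous-Poisson spike trains, seizure epochs), EDF and raw-binary
    signal I/O, cross-correlation event alignment, Hanning-taper time-frequency
    analysis with baseline percentage-change normalization, periodicity scoring
    of periodic-discharge trains, spike-train quality metrics (MAD-threshold
    detection, refractory-period violations, CV2), Gaussian-kernel peri-event
    firing-rate estimation, and cluster-based sign-flip permutation statistics
    for peri-event firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
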