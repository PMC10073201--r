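Package: dvcphase
Title: Coupled Phase-Oscillator Modelling of Circadian Rhythms in the
    Dorsal Vagal Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the three adjacent circadian oscillators of the brainstem
    dorsal vagal complex (the area postrema, the nucleus of the solitary
    tract, and the ependymal layer of the fourth ventricle) as Kuramoto-type
    phase oscillators with an AP-NTS phase lag. Simulates phase and
    phase-difference dynamics under constant or linearly decaying global
    coupling, generates synthetic PER2::LUC-like bioluminescence recordings,
    recovers instantaneous period and phase by sinc-filter detrending and
    Morlet wavelet ridge extraction, scores phase-difference stability,
    detects phase-locked segments, estimates directed coupling strengths and
    the phase lag from locked observables in closed form, and locates the
    fold bifurcation at which the synchronised state is lost.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    ggplot2,
    pracma,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
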