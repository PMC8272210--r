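Package: lfnmr
Title: Low-Field NMR Relaxometry of Oil-in-Water Emulsions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-domain low-field proton NMR relaxometry data
    from two-phase oil-in-water emulsions. Extracts biexponential
    spin-lattice (T1) and spin-spin (T2) relaxation components from
    inversion-recovery and CPMG traces, assigns short components to the oil
    phase and long components to the water phase, converts per-temperature
    R2/R1 ratios into rotational correlation times through the
    Bloembergen-Purcell-Pound dipolar relaxation model, and fits Arrhenius
    activation energies of molecular rotation per phase. Includes a
    spectrometer simulator that generates ground-truth temperature series
    for validation, and utilities for fatty-acid profile summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, yaml, jsonlite
Config/testthat/edition: 3
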