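Package: langflim
Title: Time-Resolved Autofluorescence and Reflectance Analysis for Langendorff Heart Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for time-correlated single photon counting
    (TCSPC) autofluorescence and diffuse-reflectance measurements of
    Langendorff-perfused hearts. Provides reconvolution fitting of
    bi-exponential fluorescence decays with periodic (incomplete-decay)
    excitation, instrument-response reconstruction from reference-dye
    measurements, derived metabolic metrics (intensity-weighted mean
    lifetime, short-component fraction, optical redox ratio), absorbance
    ratio metrics for tissue oxygenation and cytochrome-c state, protocol
    time-course assembly with baseline normalization and 10-90% transition
    times, and a synthetic-data generator emulating control, hypoxia and
    glucose-depletion perfusion protocols with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
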