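Package: neurosync
Title: Automated Patient-Ventilator Interaction Analysis from Diaphragm
    Electrical Activity and Airway Pressure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Breath-by-breath comparison of diaphragm electrical activity
    (EAdi) and airway pressure (Paw) waveforms for quantifying
    patient-ventilator interaction during assisted mechanical ventilation.
    Segments EAdi into neural breaths (onset, peak, 70%-of-peak cycle-off)
    and Paw into ventilator assists, matches neural efforts to assists,
    computes signed trigger and cycle-off timing errors as percentages of
    neural inspiratory and expiratory time, classifies asynchronies (wasted
    efforts, auto-triggering, double triggering, multiple EAdi bursts per
    assist, each scored as 100% error), and summarises interaction with the
    NeuroSync index (the mean per-breath percentage error). Includes a
    waveform simulator with exhaustive ground truth for validation, a
    nonparametric repeated-measures statistics layer (Friedman test with
    Dunn's post hoc, D'Agostino-Pearson normality test), exponential
    least-squares regression of wasted efforts against the decoupled index,
    plain-text file I/O, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
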