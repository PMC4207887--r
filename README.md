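# neurosync

Automated, breath-by-breath analysis of patient–ventilator interaction
from diaphragm electrical activity (EAdi) and airway pressure (Paw)
waveforms, for researchers and clinicians studying assisted (especially
non-invasive) ventilation.

Poor patient–ventilator interaction — late or early triggering and
cycling, inspiratory efforts the ventilator never rewards — is common in
COPD patients on NIV and hard to quantify by eye. This package automates
the comparison of the neural signal (EAdi) with the machine's response
(Paw):

* **neural breaths** are segmented from EAdi: onset, peak, and neural
  cycle-off at the first post-peak decay to 70% of peak;
* **ventilator assists** are segmented from Paw: pneumatic trigger and
  pneumatic cycle-off relative to PEEP;
* efforts and assists are **matched and classified** — matched,
  wasted effort, auto-trigger, double trigger, multiple EAdi per assist;
* matched breaths get signed **timing errors**,

  trigger error = 100 · (t_trig − t_onset) / Ti,n  (% of neural
  inspiratory time), and
  cycling-off error = 100 · (t_coff,vent − t_coff,neural) / Te,n
  (% of neural expiratory time; positive = late, negative = early),

  both capped at ±100%;
* each asynchronous breath is assigned **100% error**, and the
  **NeuroSync index** is the mean per-breath percentage error — 0% is
  perfect synchrony, ≤20% on both axes is "inside the synchrony box".

A waveform **simulator** with exhaustive ground truth (breath timing,
injected asynchronies, true trigger delays and cycling-off errors)
stands in for patient recordings and drives the validation suite, and a
**statistics layer** provides the repeated-measures comparison used for
mode contrasts (Friedman test with Dunn's post hoc), the
D'Agostino–Pearson normality test, and exponential least-squares
regression of wasted efforts against the index recomputed without wasted
efforts.

## Worked example

Simulate five minutes of PSV-like non-invasive ventilation and analyse
it:

```r
library(neurosync)

sim <- simulate_recording(preset_mode_config("PSV-like", seed = 42,
                                             duration_s = 420))
fit <- neurosync(sim$recording, window_s = 300)
fit
#> Automated patient-ventilator interaction analysis
#>
#>   mode: PSV-like
#>   window: 300 s, 116 neural breaths, 108 assists (PEEP 5.0 cmH2O)
#>   neural respiratory rate: 23.2 breaths/min
#>
#>   NeuroSync index: 25.2 % (without wasted efforts: 18.9 %)
#>   synchronous / dyssynchronous / asynchronous: 24.8 / 64.1 / 11.1 %
#>   breath classes: matched=104, wasted_effort=9, auto_trigger=1,
#>     double_trigger=1, multi_eadi=2
```

The index of 25.2% says the average breath carries a quarter of the
maximum timing error; the decoupled value (18.9%) is what remains after
dropping wasted efforts. `summary(fit)` adds the breathing pattern and
median (IQR) timing:

```r
summary(fit)
#>   Timing, median (IQR):
#>     trigger delay:     243 (198 to 315) ms
#>     trigger error:     24.2 (19.1 to 30.7) %
#>     cycle-off error:   -6.0 (-9.2 to -3.8) %
#>     |cycle-off|:       106 +/- 62 ms (mean +/- SD)
```

— a long pneumatic trigger delay and early cycling, the signature of
pneumatically controlled NIV in obstructed patients. A NAVA-like
simulation (`preset_mode_config("NAVA-like")`) lands near 4–5% with
almost all breaths inside the box. `plot(fit)` draws the breath-density
map of (cycling-off, trigger) errors with the 20% box, and
`as.data.frame(fit)` returns the per-breath record table.

`run_pipeline(out_dir = "results")` runs the full simulate → analyze →
report pipeline for three configured modes and writes recordings,
per-breath CSVs, report JSONs, a cross-mode summary and a run manifest;
`inst/cli/neurosync` wraps the same functions for shell use.

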