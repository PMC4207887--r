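---
title: "Methods: automated patient-ventilator interaction analysis"
author: "neurosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated patient-ventilator interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During assisted ventilation — in particular non-invasive ventilation (NIV)
of patients with COPD — the ventilator should pressurize and cycle off in
step with the patient's own inspiratory effort. The effort itself is best
observed in the diaphragm's electrical activity (EAdi, in uV, recorded by
an oesophageal electrode array); the machine's response is visible in the
airway pressure (Paw, in cmH2O). Comparing the two waveforms breath by
breath exposes both *dyssynchrony* (timing mismatch: trigger delay and
cycling-off error) and outright *asynchrony* (complete dissociation:
wasted efforts, auto-triggering, double triggering, multiple EAdi bursts
under one assist).

`neurosync()` automates that comparison. Its summary statistic, the
NeuroSync index, is the mean per-breath percentage timing error, with
every asynchronous breath scored as 100%; lower is better, and values
below roughly 20% correspond to breaths inside the "synchrony box" of the
trigger-error vs cycling-off-error plane.

## Breath-level model

**Neural breaths.** EAdi is smoothed with a short centered moving average
(48 ms, i.e. 3 samples at the 62.5 Hz acquisition rate) and referenced to
a *tonic* baseline, estimated as a sliding 10th percentile over a 10 s
window (COPD patients often show tonic diaphragm activity, so a zero
baseline cannot be assumed). Peaks are local maxima with prominence above
the baseline of at least `min_peak_uV` (default 1 uV, raised automatically
to four robust noise SDs), separated by at least 0.5 s, and distinct only
if the signal between two maxima loses at least half of the smaller
prominence — this valley rule prevents noise ripples on a burst's flanks
from splitting one effort into several. For every peak:

* **onset** — located from the crossing of `tonic + 0.10 x prominence` on
  the rising limb;
* **neural cycle-off** — the first post-peak crossing of
  `tonic + 0.70 x prominence` (the 70%-of-peak rule), linearly
  interpolated between samples;
* **ti_n** = onset to cycle-off; **te_n** = cycle-off to the next onset
  (undefined for the last breath).

Neural inspiratory time is defined onset-to-70%-decay, consistent with the
cycle-off rule; an onset-to-peak alternative can be emulated by reading
`peak_s` from the breath table. Candidate breaths shorter than
`min_ti_s = 0.3` s are rejected as noise transients.

**Ventilator assists.** Paw is referenced to PEEP (given, or estimated as
the modal value rounded to 0.5 cmH2O). A *pneumatic trigger* is a
sustained (>= 3 samples) rise of at least 1 cmH2O above PEEP; *pneumatic
cycle-off* is the fall back to 25% of the driving pressure. Both
thresholds are configurable; the defaults tolerate ~0.5 cmH2O noise.

**Sub-sample refinement.** At 62.5 Hz one sample is 16 ms — the same
order as the trigger delays of neurally triggered assist. Raw threshold
crossings therefore lag the physical events systematically (a 1 cmH2O
threshold on a 100 cmH2O/s ramp fires 10 ms late). By default
(`refine = "foot"`) the detectors locate two interpolated crossings on
the relevant limb and extrapolate their secant to the baseline (ramp
foot) or to the plateau (release onset), which removes the lag entirely
for piecewise-linear ramps and reduces it to noise level otherwise.
`refine = "crossing"` reports the literal interpolated crossings instead.

**Matching and classification.** Each trigger is assigned to the neural
breath whose onset interval contains it; intervals are shifted 0.15 s
earlier (`lead_slack_s`) so that a trigger with near-zero delay that
lands a few milliseconds before the *detected* onset is not thrown into
the previous breath. A breath with no trigger is a **wasted effort**;
with two or more, a **double trigger**. A trigger falling in no interval,
or later than the breath's cycle-off plus half its expiratory time, is an
**auto-trigger** (the te_n/2 rule is the package's disambiguation of
"late trigger" vs "dissociated assist"; it is configurable). Two or more
neural peaks between one trigger and its cycle-off mark the involved
breaths as **multiple-EAdi**. Every neural breath and every assist
appears in exactly one record.

**Errors and the index.** For matched breaths,

* trigger error = 100 x (trigger - onset) / ti_n (positive = late);
* cycling-off error = 100 x (pneumatic - neural cycle-off) / te_n
  (positive = late cycling off, negative = early);

both capped at +/-100% so no single breath can outweigh an asynchrony.
The per-breath error is the mean of the two magnitudes (an alternative
`combine = "max"` is provided; the choice is logged in the report), only
the trigger error when te_n is undefined, and exactly 100 for every
asynchronous breath. The NeuroSync index is the plain mean of the
per-breath errors; `neurosync_index(..., include_wasted = FALSE)` gives
the *decoupled* variant used when regressing wasted-effort counts on the
index, since wasted efforts enter both quantities otherwise. Whether the
20% box boundary is inclusive is not sharply defined by the convention;
the package uses `<=` (a breath at exactly 20% is synchronous).

## The simulator

No patient recordings are distributed, so validation rests on a
synthetic generator with exhaustive ground truth (`simulate_recording()`).
It emulates a COPD-like NIV recording, not any particular patient:

* **EAdi bursts**: linear rise from the tonic level over 0.75 x ti_n,
  then exponential decay whose slow time constant is chosen analytically
  so the 70%-of-peak crossing falls exactly at onset + ti_n (this gives
  the detector tests a closed-form oracle). After the 55%-of-peak level
  the decay switches to a fast constant (0.12 x ti_n) so the signal
  returns to tonic well before the next onset — without the switch the
  slow tail would bury the next onset's foot, which real post-inspiratory
  EAdi (rapid derecruitment) does not do.
* **Assists**: trapezoids from PEEP to PEEP + PS with a configurable
  pressurization ramp, held until the neural cycle-off plus a sampled
  cycling-off error, then released. Trigger delays and cycling-off errors
  are Gaussian with configurable mean and SD; the cycle-off error is
  injected relative to the neural 70% point, matching the downstream
  error definition.
* **Asynchronies**: per-breath injections, mutually exclusive with
  priority wasted > double > multiple-EAdi (keeps ground-truth labels
  single-valued); auto-triggers are placed in late expiration
  (beyond the te_n/2 dissociation boundary). The second burst of a
  multiple-EAdi event starts 0.4 s after the first breath's cycle-off so
  the two bursts are separated by a genuine valley.
* **Closed loop**: setting `pneumatic_trigger_uV` makes each assist fire
  when the EAdi ramp crosses an absolute level, and efforts that never
  reach it become wasted. Sweeping this threshold degrades trigger timing
  and *mechanically* generates wasted efforts from the lower tail of the
  peak-amplitude distribution — the mechanism behind the positive, convex
  wasted-efforts-vs-dyssynchrony relationship the validation reproduces.
* **Noise**: additive Gaussian on both channels, EAdi clipped at 0 uV.
  The flow channel is a cosmetic first-order response to (Paw - PEEP)
  and is never analysed (tidal volumes are unreliable under mask leak).

Draws occur in a fixed order and probabilities are compared against
pre-drawn uniforms, so changing one parameter does not reshuffle the
stream: parameter sweeps under a common seed are monotonically coupled.
Identical configurations (including seed) reproduce bit-identical output.

Two presets encode the qualitative mode contrast. `NAVA-like` (neurally
triggered and cycled): 50 +/- 15 ms trigger delay, +12 +/- 6 ms
cycling-off error, no wasted efforts, rare auto-triggering (0.3/min),
25 breaths/min, 24 uV peaks. `PSV-like` (pneumatically controlled NIV):
250 +/- 80 ms delay, -95 +/- 60 ms cycling-off error (early-biased, high
variance), 4.3% wasted efforts, 23 breaths/min, 26 uV peaks. The
cycling-off magnitudes, wasted fraction, rates and amplitudes follow the
published mode comparisons for this patient group; the PSV delay mean and
the SDs are not printed there and were fixed once at values typical for
pneumatically triggered NIV. What the simulator does **not** reproduce:
mask-leak pneumatics, respiratory mechanics (resistance/compliance,
intrinsic PEEP), cardiac artefacts on EAdi, or patient-specific waveform
morphology. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not clinical performance on real
recordings.

## Statistics layer

* `compare_modes()`: Friedman test on within-subject ranks across paired
  conditions (statistic referred to chi-squared, matching
  `stats::friedman.test`), with Dunn's post hoc pairwise rank-sum z
  statistics. Dunn's comparisons use Bonferroni-adjusted critical values
  and no further correction. For small designs (`exact = TRUE`, up to 8
  subjects x 4 modes) the permutation p-value is computed by enumerating
  all within-block orderings of the observed ranks, which handles ties
  naturally.
* `test_normality()`: the D'Agostino-Pearson omnibus K-squared test
  (D'Agostino's skewness z and the Anscombe-Glynn kurtosis z), requiring
  n >= 8; the implementation is verified against an independent reference
  implementation in the test suite.
* `fit_exponential()`: y = a exp(bx) by nonlinear least squares in the
  original y-space via `minpack.lm::nlsLM`, initialised from the
  log-linear fit on positive responses. Fitting in original space matches
  the stated model without down-weighting large responses; the log-linear
  alternative is available by flag and coincides with it on noiseless
  data. r-squared is computed against the mean-y baseline. An all-zero
  response returns a flagged degenerate fit (a = 0, r2 undefined) rather
  than an error.

Summaries follow the field's reporting convention — median with
interquartile range — except the absolute cycling-off milliseconds, which
are reported mean +/- SD.

## Numerical choices and degenerate inputs

* Analysis windows default to the trailing 300 s of a recording
  (`extract_analysis_window()`), clamped to the full recording when
  shorter, with `t0` preserved so event times stay on the original clock.
* Sub-sample interpolation everywhere a threshold is crossed; ties on
  flat segments resolve to the earliest sample.
* The last breath of a window has no te_n and contributes only its
  trigger error; an assist truncated by the window end is dropped.
* Empty inputs propagate as empty tables; an empty record set yields a
  report with `n_breaths = 0` and undefined (NA) indices; the NeuroSync
  index of an empty retained set is an error, not NaN.
* The quality gate (`check_signal_quality()`) refuses analysis when the
  median peak prominence is below 1 uV or fewer than 10 breaths are
  detected — the amplitude criterion that excluded low-EAdi recordings
  from automated analysis is not published, so the threshold is explicit
  and configurable, and the verdict is attached to the refusal condition.

## Validation problem sizes

The test suite validates detector-vs-ground-truth agreement on noiseless
5-minute recordings (tolerance: one sample period, 16 ms), parameter
recovery over a 36-cell grid of trigger delay {0, 50, 100, 200} ms x
cycling-off error {-100, 0, 100} ms x wasted probability {0, 0.05, 0.1}
on 5-minute recordings under a common seed, matching agreement with an
independent brute-force classifier and with exhaustive maximal-assignment
enumeration on 1000 random small instances (<= 6 x 6 events), exact
Friedman enumeration on blocks of up to 6 subjects, and a 9-point
closed-loop threshold sweep for the wasted-efforts relationship. These
sizes were chosen so the full suite completes in well under a minute per
property while keeping binomial confidence bands tight enough to be
informative (~125 breaths per 5-minute window).

## Known limitations

* The per-breath combination of trigger and cycle-off error into one
  percentage (mean of magnitudes) is one of several defensible readings
  of "averaging the percentage errors"; the max rule is provided, and
  every report logs which was used.
* The auto-trigger / late-trigger boundary (te_n/2) and the matching lead
  slack (0.15 s) are operational choices the underlying convention leaves
  open; both are configurable.
* PEEP auto-estimation assumes the baseline is the modal pressure; deep
  intrinsic-PEEP phenomena or heavy leak artefacts are out of scope.
* The simulator validates the algorithms, not the clinical claims; real
  EAdi morphology, leaks and artefacts will degrade detection in ways the
  noise model only approximates.
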