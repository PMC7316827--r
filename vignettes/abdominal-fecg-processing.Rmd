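---
title: "Processing abdominal fetal electrocardiograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing abdominal fetal electrocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetalecg)
```

# The problem

A fetal electrocardiogram (FECG) recorded from electrodes on the maternal
abdomen gives beat-to-beat fetal heart rate (FHR) non-invasively, during
both pregnancy and labour. The signal is hard to use directly: the
maternal ECG (MECG) dominates it — antenatally the maternal QRS amplitude
is typically about 3.5 times the fetal one — and what remains after
maternal suppression competes with broadband electromyographic (EMG)
noise, 50 Hz powerline pickup and baseline wander. The fetal QRS itself
rarely exceeds 20 µV on the abdomen.

`fetalecg` implements the complete processing chain for such recordings
(four abdominal channels at 500 Hz, optionally a direct scalp FECG at
1 kHz): preprocessing, MECG suppression, fetal QRS detection, signal
quality indices, detection scoring and clinical FHR reporting, together
with a calibrated synthetic record generator so every stage can be
exercised and validated without access to archived clinical recordings.

# Preprocessing: the multi-notch comb filter

Slow-changing interference and powerline pickup are removed in one pass by

$$H(z) = z^{-5d} - \frac{1}{36}\left(\frac{1-z^{-6d}}{1-z^{-d}}\right)^2,$$

with tap spacing $d = f_s/50$ samples ($d = 10$ at 500 Hz, $d = 20$ at
1 kHz), which nulls 0 Hz and every multiple of 50 Hz exactly. The
quotient is a finite geometric sum, so the filter is expanded to an
explicit linear-phase FIR (101 taps at 500 Hz) rather than implemented
recursively: this avoids the marginally stable pole–zero cancellations at
$z^{-d}=1$ and makes the nulls exact to machine precision. Both branches
share the group delay $5d$, which `comb_filter()` removes so beats stay
time-aligned with the input. The first passband edge sits near 5 Hz
(−3 dB at ≈ 4.8 Hz), which also takes out most baseline wander. Edges are
handled by reflect-padding one filter length and trimming, so outputs are
reproducible sample for sample. Rates that are not multiples of 100 Hz
are rejected rather than approximated: the notches would move off 50 Hz.

# Maternal ECG suppression

Suppression is template subtraction over the full heart cycle (PQRST),
per channel:

1. **Auxiliary MECG.** The four abdominal channels are averaged
   (`auxiliary_mecg()`). Maternal QRS complexes are coherent across
   electrodes; fetal beats and EMG average down by roughly
   $1/\sqrt{4}$. This signal is used only to locate maternal R waves.
2. **Maternal R detection** (`detect_maternal_r()`): band-passed
   derivative energy with an adaptive threshold (fraction β = 0.5 of a
   running peak level, exponential update 1/8), a 300 ms refractory
   period (maternal rate ≤ 200 bpm) and apex refinement on the raw
   auxiliary signal.
3. **Template construction** (`build_template()`): windows −250/+450 ms
   around each maternal R, covering P through T at maternal rates. The
   template is the *per-sample median* over blocks of 16 windows, with
   successive block medians blended exponentially (weight 1/2 per block)
   so it still tracks slow MECG shape change. The median matters: fetal
   QRS complexes ride the maternal cycle at effectively random offsets,
   and a plain mean template absorbs them and re-injects them (inverted)
   at subtraction time — in simulation this perturbs non-coincident
   fetal beats by 6–8 % of their amplitude, versus numerically zero with
   the median.
4. **Subtraction** (`subtract_template()`): per beat, an amplitude
   coefficient and a coefficient on the first derivative of the QRS
   portion of the template are fitted by least squares *on the QRS
   ± 50 ms window only* (the scaling is driven by QRS energy; fitting the
   T wave is unstable), then the scaled template plus derivative term is
   subtracted over the full cycle. The derivative term compensates
   sub-sample fiducial error at 500 Hz; with ±1-sample jitter it
   measurably lowers residual power. Samples between beat windows pass
   through untouched. When consecutive cycles overlap (short RR), windows
   are truncated at the midpoint between fiducials. An optional
   arrhythmia mode pools beats whose correlation with the template falls
   below 0.8 and maintains a second template for them.

# Fetal QRS detection

Detection runs on the best of the four suppressed channels, chosen by an
autocorrelation quasi-periodicity score (`periodicity_quality()`): per
4 s window, the maximum normalized autocorrelation over lags
corresponding to 110–180 bpm, averaged over windows. A clean quasi-
periodic FECG scores near 1, broadband noise near 0; periodicity outside
the fetal band (e.g. maternal residue at 80 bpm) scores low.

Since no annotated fetal template exists at run time, one is
bootstrapped (`bootstrap_fetal_template()`): a generic 40 ms sum-of-
Gaussians QRS prototype drives a normalized matched filter, the 20
strongest well-separated correlation events are sign-aligned and
averaged, and the mean is renormalized.

Three detection functions are computed (`detection_function_bank()`):

1. normalized matched filter — correlation with the template divided by
   the local signal energy over the template span. Bounded by 1
   (Cauchy–Schwarz) and invariant to channel gain, hence robust to EMG
   bursts. The local energy is floored at $10^{-4}$ of its maximum so
   near-silent spans cannot score spuriously high;
2. raw matched filter magnitude (linear);
3. band-pass 15–45 Hz → differentiate → square → 40 ms integration (the
   classical energy detector).

Each function is peak-picked adaptively (`adaptive_peaks()`: threshold
β = 0.5 of the running accepted-peak level, 200 ms refractory for rates
up to 300 bpm, a 2 s learning phase, and a search-back pass that
re-examines abnormally long inter-beat gaps at half threshold — a fetal
beat coincident with a maternal QRS loses part of its energy to the
subtraction fit and would otherwise be missed). Each peak series is then
scored by the RR-variability functional Δ, the mean absolute second
difference of its RR series, and the function with minimal Δ wins
(`select_optimal()`; ties go to the lowest index). The rationale: missed
or spurious detections make the RR series erratic, and the second
difference is insensitive to genuine slow FHR trends. Beats are finally
flagged unreliable (flag 0) when the local detection-function SNR falls
below 2 or the local Δ over a 10-beat window exceeds 3× the record
median.

For direct scalp recordings (`detect_direct_fqrs()`), normalized matched
filtering is combined with a cycle-length decision rule: the predictor is
the running median of the last five accepted RR intervals, and among
candidate peaks in the search window the one minimizing
$|RR_{\mathrm{pred}} - RR_{\mathrm{cand}}|$ is accepted. The predictor is
seeded from the dominant inter-candidate spacing, which prevents locking
onto double cycles. At 1 kHz this yields reference annotations with 1 ms
resolution.

# Amplitude-relationship (quality) indices

With maternal and fetal annotations in hand, each channel is decomposed
under two assumptions — P/T waves are small, and signal and interference
are uncorrelated:

* $P_N$: mean square outside all maternal (100 ms) and fetal (40 ms) QRS
  windows (windows are centered on the R fiducial; the symmetric choice);
* $P_M$: mean square inside *non-coincident* maternal windows minus
  $P_N$; $P_F$ analogously. Negative differences are clipped to zero and
  flagged.

Coincidence is interval overlap of the centered 100 ms and 40 ms windows.
The dB indices are $WM = 10\log_{10}(P_M/P_N)$,
$WF = 10\log_{10}(P_F/P_N)$ and $WMF = WM - WF$;
$10^{WMF/20}$ is the maternal-to-fetal amplitude ratio. Per-beat
amplitude stability is summarized by projecting each non-coincident QRS
onto the mean QRS ($r_i$) and forming WEM/WEF as the root *mean squared*
successive difference of $r_i$ divided by the mean $r_i$. The squaring
is a deliberate choice: an unsquared sum of successive differences
telescopes and its radicand can be negative, so it is dimensionally
inconsistent as a variability measure; the unsquared form remains
available as `method = "raw"` for comparison. A per-record index is the
arithmetic mean of the four per-channel values
(`record_quality_report()`), and dataset summaries are plain column means
over records (`aggregate_record_summaries()`).

Known estimator property: maternal P/T energy falls outside every QRS
window and therefore inflates $P_N$, biasing WM/WF slightly low on
signals with prominent P/T. On high-pass-filtered abdominal signals the
bias is small; the simulator's closed-loop calibration absorbs it.

# FHR analysis

Annotations convert to instantaneous FHR via $FHR_i = 60000/RR_i$ (ms).
Intervals adjacent to a flag-0 beat, or outside a 50–250 bpm physiologic
gate, are masked. The series is resampled by zero-order hold onto a 4 Hz
grid (the fetal-monitoring standard; cardiotocographs behave the same
way), and signal loss is the invalid fraction of that grid.

* **Basal FHR**: histogram mode (1 bpm bins) of a 25 s running-mean trend
  of the grid, with two exclusion iterations (±10 bpm) so acceleration /
  deceleration excursions do not drag the mode.
* **Fluctuation**: mean minute-wise peak-to-peak of the grid around the
  trend. **Oscillation**: mean minute-wise peak-to-peak of the raw grid.
* **Accelerations/decelerations**: excursions of at least ±15 bpm from
  the basal rate lasting at least 15 s (the international guideline
  convention; thresholds are arguments). Episodes already in progress at
  either record boundary are not counted, since their true extent is
  unknown.
* **Variability indices**: epochs of 3.75 s (16 per minute, the
  Dawes–Redman convention); STV = mean absolute difference of adjacent
  epoch mean RR, LTV = mean minute-wise epoch range. LTI (de Haan) =
  IQR of $\sqrt{RR_i^2+RR_{i+1}^2}$; STI (de Haan) = IQR of
  $\arctan(RR_{i+1}/RR_i)$; II (Yeh) = minute-wise coefficient of
  variation of RR, averaged; DI (Yeh) = minute-wise SD of
  $1000\,(RR_i-RR_{i+1})/(RR_i+RR_{i+1})$, averaged. Commercial
  monitoring systems do not publish their exact variants of the basal /
  fluctuation / STI algorithms, so these literature-standard definitions
  are validated by simulation recovery (programmed baseline and episode
  counts are recovered exactly; reported STV rises monotonically with
  programmed beat-to-beat jitter), not against any particular vendor's
  output.

# Detection scoring

`match_beats()` pairs test and reference beats one-to-one within a
±40 ms tolerance (about one fetal QRS width), by dynamic programming
that maximizes the number of matches and, among those, minimizes the
total absolute offset. This is deterministic and optimal, unlike greedy
nearest-neighbour pairing; on small instances it is verified against
exhaustive enumeration. From TP/FP/FN come PI, Acc, Se, PPV and F1 (both
printed forms of F1 agree identically). RR accuracy (ΔRR) is evaluated
only on intervals whose both endpoints are matched, which avoids
artifacts from gaps; a constant detection latency therefore cancels, as
it should for a rate-accuracy measure.

# The synthetic record generator

`generate_record()` emulates the antenatal measurement scenario: four
abdominal channels (500 Hz) mixing a maternal train (default 80 bpm,
8 ms jitter) and a fetal train with a programmable FHR profile
(baseline, raised-cosine accelerations/decelerations, sinusoidal
oscillation, beat-to-beat jitter σ = 3 ms by default), plus three
switchable noise classes: band-limited (20–150 Hz) Gaussian EMG (2 µV
RMS default), a fixed 50 Hz sinusoid (1 µV) and 0.2–0.8 Hz baseline
wander (5 µV). Morphologies are sums of Gaussians in the dynamical-model
tradition; the fetal QRS is ≈ 40 ms wide, the maternal ≈ 100 ms, with P/T
rendered at the attenuated level seen in abdominal leads after the
recorder's analog high-pass. A direct fetal channel at 1 kHz (30 µV,
0.5 µV noise) mirrors its gold-standard role.

Amplitudes are *calibrated in a closed loop*: the generator scales the
maternal and fetal components until the package's own
`record_quality_report()` applied to the emitted record, with the
ground-truth annotations, reports the requested WM and WF (defaults
14.3 dB and 3.4 dB, the antenatal dataset means; with the default noise
floor the calibrated fetal R amplitude stays under 20 µV). Open-loop
scaling would miss by up to ~1 dB because of the P/T bias discussed
above. Noiseless records ($P_N = 0$) cannot express dB targets and use
fixed amplitudes instead. Component traces are stored and sum exactly to
the emitted mixture, and a given seed reproduces a record bit for bit.

What the simulator does *not* model: volume-conductor electrophysiology
and electrode geometry, uterine-contraction artifacts, electrode drop-
outs, maternal arrhythmia, twins. Passing the simulation suite therefore
demonstrates correctness of the algorithms under controlled amplitude
relations and FHR patterns — not clinical performance on real abdominal
recordings, whose EMG is non-stationary and whose morphologies vary.

# Numerical choices and problem sizes

Tolerances and constants not already covered: annotation files store
1-based sample numbers (a `one_based = FALSE` reader argument handles
0-based exports); signals are written with 6 significant digits;
matching tolerance is inclusive (an offset of exactly 40 ms matches);
ties in channel and function selection go to the lowest index. The
validation suite uses 10-minute records for end-to-end detection and for
the 4 × 4 (WM × WF) calibration grid, and 2–5 minute records for
stage-level tests; these sizes give stable statistics (about 1400 fetal
beats per 10-minute record) while keeping the suite quick to run.

# Worked example

```{r example}
library(fetalecg)

cfg <- sim_config(duration_s = 600, seed = 1)     # WM 14.3 dB, WF 3.4 dB
rec <- generate_record(cfg)

res <- process_record(rec$bundle)                 # comb -> subtract -> detect
round(res$performance, 2)                         # PI, Acc, Se, PPV, F1
res$rr_accuracy                                   # |dRR| in ms and bpm

record_quality_report(rec$bundle)                 # WM/WF/WMF, WEM/WEF
fhr_report(res$fetal_r, duration_ms = 600000)     # clinical FHR report
```

The same chain is what `scripts/acceptance.R` runs from scratch; see the
README for how to reproduce its numbers.
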