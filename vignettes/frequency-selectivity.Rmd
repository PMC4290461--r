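---
title: "Measuring auditory frequency selectivity with SFOAE suppression and fast psychophysical tuning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory frequency selectivity with SFOAE suppression and fast psychophysical tuning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaetune)
```

## The measurement problem

Frequency selectivity (FS) is the ear's ability to resolve the tonal
components of a complex sound. It is set mainly by the mechanical tuning of
the basilar membrane, which behaves like a bank of band-pass filters whose
sharpness depends on healthy outer-hair-cell amplification. FS is summarized
by a tuning curve -- the level of an interfering tone or noise needed, at each
frequency, to produce a fixed effect on a probe tone -- and by the curve's
`Q10`: tip frequency divided by the bandwidth 10 dB above the tip.

Two routes to the same quantity:

* **Behavioral (subjective)**: a psychophysical tuning curve (PTC). The
  listener reports whether a fixed, low-level probe tone is audible while a
  narrowband masker sweeps slowly in frequency; Bekesy-style tracking (masker
  level rises while the probe is audible, falls while it is not) traces the
  masked threshold.
* **Otoacoustic (objective)**: a stimulus frequency otoacoustic emission
  (SFOAE) suppression tuning curve (STC). A continuous probe tone evokes an
  emission from the cochlea at the same frequency; a second tone suppresses it
  by an amount that depends on the suppressor's frequency and level. The
  suppressor level producing a fixed criterion suppression, per frequency, is
  a tuning curve of the emission generation site. Because no behavioral
  response is needed, STCs can in principle assay FS in listeners who cannot
  respond (neonates, comatose patients).

This package implements both pipelines end to end -- stimulus synthesis,
acquisition, curve extraction, metrics, and the comparative statistics --
with a parametric *virtual ear* and *virtual listener* in place of hardware
and human subjects, so that every stage can be validated against known ground
truth.

## The SFOAE pipeline

### Six-section paradigm and the four-buffer residual

A single acquisition interleaves six stimulus sections: a lead-in `M` of
duration `2*T_d` (`T_d` = 14.5 ms, the sound-output-to-input system delay)
followed by `N, A, B, C, D` of `T_w` = 50 ms each. The probe is a continuous
tone of constant polarity throughout; the suppressor is silent except for a
5-ms cosine-gated burst in section `C` and its exact sample-wise negation in
`D`. The recorded ear-canal sections are stored in four buffers:

| buffer | contents |
|---|---|
| A, B | probe artifact `Rp` + emission `SFE` |
| C | `Rp` + suppressor artifact `Rs` + suppressor-evoked emission `SFEs` + suppressed emission `SFE'` |
| D | `Rp` - `Rs` - `SFEs` + `SFE'` |

The residual

$$ r = \tfrac{1}{2}\left[(A + B) - (C + D)\right] = SFE - SFE' $$

cancels `Rp`, `Rs` and `SFEs` *algebraically*, to numerical precision, for
any artifact waveforms that respect the polarity scheme. The factor 1/2 makes
the full-suppression residual equal the probe-evoked emission itself. The
residual is high-pass filtered (zero-phase forward-backward 4th-order
Butterworth, 500 Hz cutoff, reflection-padded to suppress edge transients),
trimmed to a whole number of probe periods, and read out at the FFT bin
nearest the probe frequency; the noise floor is the median amplitude of
neighbouring bins. 64 sub-averages are folded in by default.

Exact probe cancellation across buffers requires the probe frequency to be an
integer multiple of `1/T_w` (20 Hz at the defaults); the 40-Hz fine-structure
grid used to choose the probe satisfies this automatically.

### Protocol

1. **Fine structure** (`run_fine_structure`): emission amplitude on an
   11-point, 40-Hz grid spanning the characteristic frequency (CF) ± 200 Hz;
   the best probe frequency `f_p` is the argmax (ties resolved toward the
   CF). All later stages use this `f_p` with a 30 dB SPL probe.
2. **I/O function** (`run_io_function`): emission level for probe levels
   5-50 dB SPL in 5-dB steps; compressive growth confirms a healthy,
   measurable emission and anchors the criterion.
3. **STC** (`build_stc`): the "total" emission is measured with the standard
   reference suppressor (47 Hz below `f_p`, 70 dB SPL). Then, per suppressor
   frequency on a geometric grid (10 points/octave; 0.5-2.5 `f_p` at a CF of
   1 kHz, 0.5-1.75 `f_p` at 2 and 4 kHz), the suppressor level is bisected
   until the residual sits -6 dB re the total (half suppression, since
   `20*log10(1 - 1/2) = -6.02` dB), to a 0.5-dB tolerance within a 0-90 dB
   SPL bracket. Unattainable points are kept as gaps; a curve with fewer than
   three valid points is rejected.

Bisection (rather than an up-down staircase) is used for level tracking
because each virtual acquisition is cheap and the suppression growth is
monotone; the tolerance (0.5 dB) is well below the curve features of
interest. The "total SFOAE" convention -- the residual under the reference
suppressor -- is an interpretation: that suppressor does not suppress fully
for very sharp filters, which shifts every tracked level by the same
constant number of decibels and therefore leaves the curve *shape* (tip
frequency, Q10) unchanged.

## The fast PTC pipeline

### Stimuli

The probe is pulsed (700-ms cycles: 200-ms gap + 500-ms tone with 20-ms
raised-cosine ramps; 350 cycles, 245 s) to help the listener hold attention.
The masker is a 240-s narrowband noise of bandwidth `0.2*f_p` (capped at
320 Hz), built from 750 segments of 640 ms at 50% overlap under a Hann
window `0.5*(1 - cos(2*pi*t/T))` -- Hann windows at exactly half overlap sum
to a constant amplitude envelope. Segment centre frequencies form a
geometric ladder with ratio 1.00185 (reciprocal for the downward sweep),
spanning a factor `1.00185^749 ~ 4`, i.e. one octave either side of the
probe. Each segment is synthesized as the inverse FFT of a low-pass Gaussian
noise of bandwidth `B/2`, modulated by a sine at the centre frequency, then
RMS-normalized; per-segment RMS is scaled by `1/sqrt(0.75)` (the mean squared
50%-overlapped Hann pair) so the overlap-added long-term level matches the
commanded level. The masker starts 5 s after the probe; its level moves at
2 dB/s under listener control and is capped at 90 dB SPL.

### Analysis

The raw curve samples the commanded masker level at each segment's temporal
centre, mapped to that segment's centre frequency (lead-in excluded).
Turning points are found by convolving the levels with `[1, -2, 1]` (a
discrete second difference): points where the result exceeds `1e-9` dB in
magnitude mark reversals; the first and last samples are always included so
the smoothed curve spans the sweep. The smoothed curve is the sequence of
midpoints (in frequency and level) of adjacent turning-point pairs -- for an
ideal triangle track this is exactly the midline, i.e. the masked threshold.
The tip is the smoothed minimum (ties -> geometric mean of tied
frequencies). Because sweeping drags the tip in the sweep direction, each
sweep's frequency axis is normalized by its own tip, the two curves are
averaged on a common grid (10 points/octave in normalized log-frequency,
matching the STC resolution), and the averaged tip is mapped to the
geometric mean of the two tip frequencies -- so opposite drags cancel to
first order.

## The virtual ear and listener

The generative models provide inputs with known ground truth. They are
phenomenological -- they reproduce the *observable regularities* an analysis
pipeline must cope with, not cochlear mechanics.

**Ear model** (`ear_model`):

* *Compressive I/O*: emission level grows 1 dB/dB below a 30 dB SPL knee,
  bending smoothly to 0.3 dB/dB above it; baseline gain -20 dB re the probe
  (a 30-dB probe evokes roughly an 8 dB SPL emission).
* *Fine structure*: a sinusoidal ripple of emission level vs frequency
  (period 800 Hz, depth 6 dB) peaking at `1.05*CF` by default, giving a
  well-defined best frequency slightly above the nominal CF.
* *Two-tone suppression*: the suppressed fraction is logistic in suppressor
  level (slope 3 dB) about a V-shaped 50%-suppression contour
  `L50(f_s) = 45 dB + atten(f_s)`, where the attenuation is a
  rounded-exponential (roex) weight `(1 + p|g|) e^{-p|g|}` in octave distance
  `g` from a tip at `(1 + 0.12) f_p`. The slope `p` is calibrated in closed
  form so the contour's Q10 equals `filter_q10` exactly; the 12% basal tip
  shift mirrors the upward displacement of emission suppression tuning
  relative to the probe place. Because the criterion contour of a logistic
  family is a *vertical translation* of `L50`, the recovered curve shape is
  insensitive to the exact criterion or reference convention.
* *Acquisition*: linear stimulus leak-through (gain 1), a 5-ms emission
  latency (pure phase rotation), and additive white Gaussian noise (0 dB SPL
  broadband by default, i.e. roughly -40 dB SPL at the analysis bin after 64
  sub-averages -- far below the emission, as in a good clinical recording).

**Listener model** (`listener_model`): a power-spectrum masking rule. The
probe is audible while its level exceeds the masker level, attenuated by a
roex auditory filter centred at `f_p` (sharpness `auditory_filter_q10`,
same closed-form calibration), by more than `threshold_snr_db` (-15 dB
default, placing the PTC tip at 45 dB SPL for a 30-dB probe). The masker is
treated as spectrally compact at its centre frequency: integrating masker
power across the 0.2-`f_p` noise band inside the filter would smear the
measured tip by roughly the noise bandwidth -- a real phenomenon in
behavioral data -- but would break the exact correspondence between the
listener's filter Q10 and the PTC Q10 that closed-loop validation relies
on, so band smearing is deliberately not emulated. Responses are delayed by
300 ms plus 50-ms Gaussian jitter; the tracking loop runs on a 50-ms grid.

**What the virtual pair does not emulate** (so passing tests do not certify
it): multiple reflection sources and emission phase rotation with frequency,
spontaneous emissions interfering with detection, middle-ear transfer,
attention lapses and response bias beyond Gaussian jitter, level-dependent
broadening of cochlear tuning, and masker-bandwidth smearing of PTC tips.
Recovery tolerances obtained on virtual data bound the *pipeline's* error,
not the biological variability of real ears.

## Numerical choices and degenerate inputs

* Default sample rate 48 kHz: every stimulus component stays below 8 kHz, so
  the full protocol runs at desk scale; the rate is configurable throughout.
* Probe phases are generated with exact integer modular arithmetic per
  section, so congruent sections are bitwise identical and the no-noise,
  no-suppressor acquisition gives exactly equal buffers.
* The residual is trimmed to whole probe periods before the FFT
  (rectangular window, no leakage at the probe bin); the readout bin is the
  one nearest `f_p`.
* Missing STC points stay as gaps; Q10's flank interpolation (linear in
  `log2 f` vs dB) bridges single gaps but a flank that never reaches
  `L_tip + 10` dB makes Q10 undefined and the curve is excluded from
  summaries.
* Flat smoothed curves have no tip (flagged); monotone raw curves degenerate
  to themselves in smoothing (flagged); all-equal fine-structure amplitudes
  resolve the best-frequency tie toward the CF.
* Every stochastic operation takes a seed and is bit-reproducible; pipeline
  closures derive consecutive per-acquisition seeds from a base seed.

## Comparative statistics

`q10_statistics` reproduces the group comparison on a Q10 table (the
packaged `table1.csv` holds 10 normal-hearing subjects at CFs of 1, 2 and
4 kHz): per-CF means and sample SDs of both measures, a two-sided paired t
test on the 30 STC-PTC pairs, per-CF PTC/STC ratio summaries after
excluding aberrant ratios above 1.5 (a reconstruction validated by
reproducing the published ratio means, SDs and ANOVA degrees of freedom),
and a one-way ANOVA of the retained ratios across CFs. `paired_t` and
`oneway_anova` are implemented from their closed forms and are cross-checked
against `stats::t.test` and `stats::aov` to 1e-10 in the test suite. The
vertical offset ratio divides dB levels as plain numbers -- dB is a log
unit, so this is a convention, followed deliberately.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: residual
cancellation against directly constructed buffers; level tracking against a
dense 0.1-dB scan of the generative suppression function; turning-point
detection against a slope-sign-change oracle on random staircases; Q10
against closed forms for log-symmetric V curves; the statistics against the
reference library. Closed-loop recovery sweeps run the full STC and PTC
pipelines at generating Q10 values of 3, 5 and 8 (three seeds each, CF
1 kHz, 64 sub-averages) and require Q10 recovery within 15% and the STC tip
within 3% of `1.12 f_p`; the grid quantization of 10 points/octave
(~7% spacing) dominates both error budgets. These sizes keep a full
validation run in the tens of seconds while exercising the protocol at its
standard resolution.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(cf = 4000, seed = 42)
bundle <- run_experiment(cfg)
bundle$metrics
plot(bundle$stc)
plot(bundle$ptc, add = TRUE, col = 2)
write_bundle(bundle, "cf4000")
```

The bundle contains the fine structure, I/O function, both tuning curves,
the tracking records, a one-row metrics table (`f_p`, both Q10 values, tip
offsets) and a provenance log (config hash, seed, package version, per-stage
timings) sufficient to replay the run.

## Known limitations

* The STC's absolute level axis inherits the reference-suppressor
  convention; cross-study comparison of tip *levels* should account for it
  (tip frequencies and Q10 are unaffected).
* The discrete suppressor grid quantizes the STC tip to ~7% steps; with the
  12% generative tip shift the nearest grid point sits 2.6% high, which is
  visible in the recovered horizontal offsets.
* Up/down PTC tip drags are only a few tenths of a percent at the default
  reaction time, so the benefit of two-direction averaging, while
  measurable in aggregate, is small compared with single-run scatter.
* The virtual listener's compact-masker approximation makes PTCs slightly
  sharper than a band-integrating listener would produce.
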