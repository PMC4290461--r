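# oaetune

Dual assessment of human auditory **frequency selectivity (FS)**: objective
**SFOAE suppression tuning curves (STCs)** and subjective **fast
psychophysical tuning curves (PTCs)**, from stimulus synthesis through
tuning-curve extraction to the comparative statistics — with a parametric
virtual ear and virtual listener standing in for hardware and human
subjects.

FS is the ear's ability to resolve the tonal components of complex sound,
summarized by the sharpness of a tuning curve:

- **PTC**: the masker level `L_m(f_m)` that just masks a fixed probe tone
  (`f_p`, `L_p`), measured behaviorally with Bekesy tracking of a swept
  narrowband masker (750 Hann-windowed segments at 50% overlap, centre
  frequency ratio 1.00185/segment, ±1 octave about `f_p` in 240 s).
- **STC**: the suppressor level `L_s(f_s)` that reduces the stimulus
  frequency otoacoustic emission by a fixed criterion (−6 dB, i.e. half
  suppression, since `20·log10(1 − 1/2) = −6.02 dB`). The emission is
  isolated by the four-buffer residual of a six-section probe/suppressor
  paradigm,

  `r = [(A + B) − (C + D)] / 2`,

  which cancels the probe artifact, suppressor artifact and
  suppressor-evoked emission exactly.

Both curves are summarized by `Q10 = f_tip / BW10` (bandwidth 10 dB above
the tip) and by horizontal/vertical tip offsets re `(f_p, L_p)`; a cohort
table of Q10 values (10 normal-hearing subjects × CFs of 1, 2 and 4 kHz)
ships as a fixture, and `q10_statistics()` reproduces the group comparison
(paired t test, PTC/STC ratio summaries with aberrant-point exclusion,
one-way ANOVA across CFs).

Intended users: auditory researchers prototyping or validating
emission-based FS assessment, and anyone needing a fully synthetic,
ground-truth-controlled test bench for tuning-curve pipelines.

## Worked example

```r
library(oaetune)

cfg <- run_config(cf = 4000, seed = 42)   # virtual ear + listener defaults
bundle <- run_experiment(cfg)
bundle
#> <run_bundle> CF 4000 Hz | f_p 4200 Hz, L_p 30 dB SPL
#>   STC: tip 4824.5 Hz @ 46.2 dB, Q10 4.70
#>   PTC: tip 4203.9 Hz @ 44.6 dB, Q10 5.20
```

Reading this: fine structure found the best probe frequency at 4200 Hz (the
virtual ear's emission peak, 1.05 × CF). The STC tip sits ~15% above `f_p`
(the generative suppression filter is tipped 12% basal, plus ~2.6% grid
quantization at 10 points/octave), while the PTC tip coincides with `f_p` —
the characteristic signature separating the two measures. The Q10 values
(4.70 objective vs 5.20 behavioral) recover the generating filter
sharpness (5) within the pipeline's tolerance.

Cohort statistics on the packaged Q10 table:

```r
s <- q10_statistics(read_q10_table())
round(s$paired_t$t, 3); round(s$paired_t$p, 3)
#> [1] -2.411
#> [1] 0.022
round(s$ratio_summary$mean_ratio, 3)
#> [1] 1.058 1.099 1.054
```

The PTC/STC Q10 ratios stay near 1 across CFs (ANOVA F(2,24) ≈ 0.16), i.e.
the objective measure tracks the behavioral one at the group level.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/oaetune.R run --config cfg.yaml --out outdir
Rscript inst/cli/oaetune.R synth masker --config cfg.yaml --out masker.wav
Rscript inst/cli/oaetune.R metrics --out stats.json
```

## Package layout

- `R/stimulus.R` — probe trains, narrowband segments, masker sweeps, the
  six-section SFOAE paradigm
- `R/virtual_ear.R` — generative ear (compressive I/O, fine structure,
  roex suppression filter) and listener (power-spectrum masking, reaction
  delay) models
- `R/sfoae.R` — four-buffer residual extraction, fine structure, I/O
  function, critical-level tracking, STC construction
- `R/ptc.R` — tracking records, raw curves, `[1,−2,1]` turning-point
  smoothing, tip estimation, up/down sweep averaging
- `R/metrics.R` — Q10, offset ratios, ratio summaries, paired t, one-way
  ANOVA
- `R/io.R`, `R/run.R`, `R/audio.R` — file formats (WAV/CSV/YAML/JSON),
  the end-to-end runner, audio containers
- `vignettes/frequency-selectivity.Rmd` — the methods account: models,
  assumptions, parameter choices, validation strategy, limitations
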