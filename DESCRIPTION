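Package: oaetune
Title: Objective and Behavioral Assessment of Auditory Frequency Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating human auditory frequency selectivity by two
    complementary routes: objective suppression tuning curves (STCs) built from
    stimulus frequency otoacoustic emissions (SFOAEs) recorded with a
    four-buffer two-tone suppression paradigm, and subjective fast
    psychophysical tuning curves (PTCs) obtained from Bekesy-style tracking of
    a swept narrowband masker. Includes full stimulus synthesis (pulsed probe
    trains, overlap-add narrowband masker sweeps, the six-section
    probe/suppressor paradigm), a parametric virtual ear and virtual listener
    for closed-loop validation with known ground truth, SFOAE residual
    extraction with fine structure and input/output functions, tuning-curve
    metrics (Q10, tip offset ratios), and the comparative statistics (paired t
    test, one-way ANOVA, Q10-ratio summaries with aberrant-point exclusion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
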