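test_that("probe train has the specified cycle structure and level", {
  # full-scale config: 350 cycles of 700 ms = 245 s
  pt <- synth_probe_train(probe_config(1000, 30), 48000)
  expect_equal(duration_s(pt), 245)

  # single cycle: 0.2 s silence then a 0.5-s gated tone
  one <- synth_probe_train(probe_config(1000, 30, n_cycles = 1), 48000)
  expect_equal(duration_s(one), 0.7)
  expect_true(all(one$samples[1:(0.2 * 48000)] == 0))
  expect_true(any(one$samples[(0.2 * 48000 + 1):(0.7 * 48000)] != 0))

  # tone plateau RMS corresponds to L_p within 0.1 dB
  plateau <- one$samples[(0.25 * 48000):(0.65 * 48000)]
  expect_equal(level_db_spl(plateau), 30, tolerance = 0.1 / 30)

  expect_error(synth_probe_train(probe_config(30000, 30), 48000),
               class = "oaetune_aliasing")
})

test_that("narrowband segments concentrate power in band and are reproducible", {
  s <- synth_narrowband_segment(1000, 200, 0.64, 48000, 60, seed = 1)
  p <- Mod(stats::fft(s$samples))^2
  n <- length(s$samples)
  fr <- (seq_len(n) - 1) * 48000 / n
  half <- fr <= 24000
  inband <- sum(p[half & fr >= 900 & fr <= 1100]) / sum(p[half])
  expect_gt(inband, 0.95)
  expect_equal(level_db_spl(s), 60, tolerance = 1e-8)

  # degenerate one-bin band: a pure (possibly sign-flipped) tone at f_center
  s2 <- synth_narrowband_segment(1000, 1 / 0.64, 0.64, 48000, 60, seed = 2)
  t <- (seq_len(length(s2$samples)) - 1) / 48000
  expect_gt(abs(stats::cor(s2$samples, sin(2 * pi * 1000 * t))), 1 - 1e-9)

  # determinism contract
  a <- synth_narrowband_segment(2000, 300, 0.2, 48000, 50, seed = 7)
  b <- synth_narrowband_segment(2000, 300, 0.2, 48000, 50, seed = 7)
  expect_identical(a$samples, b$samples)

  expect_error(synth_narrowband_segment(23900, 400, 0.1, 48000),
               class = "oaetune_aliasing")
})

test_that("masker sweep geometry: 750 half-overlapped 640-ms segments over 2 octaves", {
  cfg <- masker_config(1000, "up")
  expect_equal(cfg$f_i[750] / cfg$f_i[1], 1.00185^749)
  expect_equal(1.00185^749, 4, tolerance = 0.01)
  # ladder strictly monotone, endpoints bracket f_p symmetrically in log-f
  expect_true(all(diff(cfg$f_i) > 0))
  expect_equal(sqrt(cfg$f_i[1] * cfg$f_i[750]), 1000, tolerance = 1e-9)
  # downward sweep is the reciprocal ladder
  dn <- masker_config(1000, "down")
  expect_equal(dn$f_i, rev(cfg$f_i))

  m <- synth_masker_sweep(cfg, level_track = 60, sample_rate = 8000, seed = 5)
  expect_equal(duration_s(m$signal), 240.32)
  expect_equal(nrow(m$trajectory), 750)
  expect_equal(m$trajectory$f_hz, cfg$f_i)

  # constant commanded level: long-term RMS flat across the sweep interior
  sr <- 8000
  t0s <- seq(10, 225, by = 5)
  w <- vapply(t0s, function(t0) {
    level_db_spl(m$signal$samples[(t0 * sr):((t0 + 5) * sr)])
  }, numeric(1))
  expect_lt(max(abs(w - 60)), 0.5)

  # levels above the 90 dB SPL ceiling are clipped with a warning
  cfg_s <- masker_config(1000, "up", n_segments = 4)
  expect_warning(
    ms <- synth_masker_sweep(cfg_s, level_track = c(80, 95, 85, 92),
                             sample_rate = 8000, seed = 1),
    "clipping"
  )
  expect_equal(ms$trajectory$level_db, c(80, 90, 85, 90))
})

test_that("Hann windows at 50% overlap sum to a constant envelope", {
  n <- 512
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  env <- numeric(n * 6)
  for (k in 0:10) env[k * n / 2 + seq_len(n)] <- env[k * n / 2 + seq_len(n)] + w
  interior <- env[(n + 1):(4.5 * n)]
  expect_lt(20 * log10(max(interior) / min(interior)), 1e-9)
})

test_that("six-section paradigm: polarity scheme, timing, and ramps", {
  stim <- synth_sfoae_paradigm(1000, 30, suppressor_config(1300, 70))
  # total duration 2*T_d + 5*T_w = 0.279 s at defaults
  expect_equal(duration_s(stim$signal), 0.279)
  n_w <- round(stim$T_w * 48000)
  supp <- stim$signal$samples[, "suppressor"]
  secs <- stim$section_boundaries
  # suppressor silent in M, N, A, B
  expect_true(all(supp[seq_len(secs[["C"]] - 1)] == 0))
  # section D suppressor is the exact sample-wise negation of section C
  c_burst <- supp[secs[["C"]] - 1 + seq_len(n_w)]
  d_burst <- supp[secs[["D"]] - 1 + seq_len(n_w)]
  expect_identical(d_burst, -c_burst)
  expect_true(any(c_burst != 0))
  # probe plateau level matches L_p
  expect_equal(level_db_spl(stim$signal$samples[, "probe"]), 30,
               tolerance = 0.01)
  # disabled suppressor leaves the channel silent
  stim0 <- synth_sfoae_paradigm(1000, 30, suppressor_config(1300, -Inf))
  expect_true(all(stim0$signal$samples[, "suppressor"] == 0))
  # sections must be long enough for the gating ramps
  expect_error(
    synth_sfoae_paradigm(1000, 30, suppressor_config(1300, 70, ramp_ms = 30),
                         T_w = 0.05),
    class = "oaetune_bad_config"
  )
})
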