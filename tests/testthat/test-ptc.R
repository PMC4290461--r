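make_track <- function(level_fun, n_seg = 100, f0 = 800, ratio = 1.00185,
                       lead_in = 5, sweep_dir = "up") {
  t_seg <- lead_in + (seq_len(n_seg) - 1) * 0.32 + 0.32
  t_lev <- seq(0, max(t_seg) + 1, by = 0.05)
  tracking_record(
    events = data.frame(time_s = c(0.1, 50), event = c("press", "release")),
    level_traj = data.frame(time_s = t_lev, level_db = level_fun(t_lev)),
    freq_traj = data.frame(time_s = t_seg, segment = seq_len(n_seg),
                           f_hz = f0 * ratio^(seq_len(n_seg) - 1)),
    sweep_dir = sweep_dir, f_p = 1000, L_p = 30, lead_in_s = lead_in
  )
}

test_that("raw curves sample the level at segment centres, after the lead-in", {
  # triangle about 50 dB; ladder ascends by 1.00185 per segment
  tr <- make_track(function(t) 50 + 2 * (abs((t / 4) %% 2 - 1) - 0.5))
  raw <- record_to_raw(tr)
  expect_equal(length(raw$levels), 100)
  expect_equal(raw$frequencies[2] / raw$frequencies[1], 1.00185)
  expect_lt(max(abs(raw$levels - 50)), 1.01)

  # segments whose centres fall inside the 5-s lead-in are excluded
  tr2 <- make_track(function(t) rep(60, length(t)), lead_in = 5)
  tr2$freq_traj$time_s <- tr2$freq_traj$time_s - 10 # push 30 segments early
  n_early <- sum(tr2$freq_traj$time_s < 5)
  expect_gt(n_early, 0)
  raw2 <- record_to_raw(tr2)
  expect_equal(length(raw2$levels), 100 - n_early)

  tr$events <- tr$events[0, ]
  expect_error(record_to_raw(tr), class = "oaetune_bad_record")
})

test_that("two-point smoothing of a staircase triangle recovers its midline", {
  raw <- make_triangle_raw(n = 61, half = 5, lo = 40, hi = 44)
  sm <- smooth_raw(raw)
  expect_false(sm$degenerate)
  # midpoints of adjacent extrema all sit on the midline
  interior <- sm$levels[2:(length(sm$levels) - 1)]
  expect_true(all(abs(interior - 42) < 1e-9))
})

test_that("turning points match a brute-force slope-sign-change oracle", {
  set.seed(33)
  for (i in 1:10) {
    n <- 40
    # constant-rate staircase (fixed 0.64 dB per step, random direction),
    # like a Bekesy track sampled per segment
    lev <- 50 + cumsum(sample(c(-1, 1), n, TRUE)) * 0.64
    raw <- structure(list(frequencies = 1000 * 1.002^(1:n), levels = lev,
                          sweep_dir = "up", f_p = 1000, L_p = 30),
                     class = "raw_curve")
    sm <- smooth_raw(raw)
    # oracle: interior points where the slope changes sign
    slopes <- sign(diff(lev))
    oracle <- 1 + which(slopes[-1] != slopes[-(n - 1)])
    expect_equal(setdiff(sm$turning_points, c(1L, n)), oracle)
  }
})

test_that("smoothing handles degenerate and near-flat inputs", {
  # strictly monotone ramp: no interior turning points, flagged
  ramp <- structure(list(frequencies = 1000 * 1.002^(1:20),
                         levels = seq(40, 59, by = 1),
                         sweep_dir = "up", f_p = 1000, L_p = 30),
                    class = "raw_curve")
  sm <- smooth_raw(ramp)
  expect_true(sm$degenerate)
  expect_equal(sm$levels, ramp$levels)

  # numerical plateaus (1e-12 dB wobble) spawn no spurious turning points
  plateau <- ramp
  plateau$levels <- 50 + rep_len(c(0, 1e-12, -1e-12), 20)
  smp <- smooth_raw(plateau)
  expect_true(smp$degenerate)

  expect_error(smooth_raw(list(frequencies = 1:2, levels = 1:2)),
               class = "oaetune_bad_curve")
})

test_that("smoothing is equivariant to level and log-frequency shifts", {
  raw <- make_triangle_raw(n = 45, half = 4)
  base <- smooth_raw(raw)
  shifted <- raw; shifted$levels <- raw$levels + 7.5
  sm_s <- smooth_raw(shifted)
  expect_equal(sm_s$levels, base$levels + 7.5)
  expect_equal(sm_s$frequencies, base$frequencies)
  scaled <- raw; scaled$frequencies <- raw$frequencies * 2
  sm_k <- smooth_raw(scaled)
  expect_equal(sm_k$frequencies, base$frequencies * 2)
  expect_equal(sm_k$levels, base$levels)
})

test_that("tip estimation: minimum, geometric-mean tie rule, flat flag", {
  v <- structure(list(frequencies = c(800, 900, 1000, 1100, 1200),
                      levels = c(60, 40, 25, 42, 61)),
                 class = "smoothed_curve")
  expect_equal(estimate_tip(v), list(f_tip = 1000, L_tip = 25))

  tie <- v; tie$levels <- c(60, 30, 50, 30, 61)
  tip <- estimate_tip(tie)
  expect_equal(tip$f_tip, sqrt(900 * 1100))

  flat <- v; flat$levels <- rep(33, 5)
  expect_error(estimate_tip(flat), class = "oaetune_no_tip")
})

test_that("sweep averaging is idempotent and symmetrizes tip offsets", {
  f <- 1000 * 2^seq(-0.8, 0.8, by = 0.05)
  shape <- function(ff, tip_f) 30 + 18 * abs(log2(ff / tip_f))
  mk <- function(tip_f) structure(
    list(frequencies = f * tip_f / 1000, levels = shape(f * tip_f / 1000, tip_f),
         degenerate = FALSE, sweep_dir = "up", f_p = 1000, L_p = 30),
    class = "smoothed_curve"
  )
  # identical sweeps: output equals input up to grid interpolation
  avg_same <- average_sweeps(mk(1000), mk(1000))
  expect_equal(avg_same$f_tip, 1000, tolerance = 1e-6)
  ref <- approx(log2(f / 1000), shape(f, 1000), xout = log2(avg_same$frequencies / 1000))
  expect_equal(avg_same$levels, ref$y, tolerance = 1e-6)

  # opposite 5% tip offsets with the same shape: averaged tip at the
  # geometric mean, ~f_p
  avg <- average_sweeps(mk(1050), mk(950))
  expect_equal(avg$f_tip, sqrt(1050 * 950), tolerance = 1e-6)
  expect_equal(avg$f_tip, 1000, tolerance = 0.002)
})

test_that("the averaged PTC recovers the listener's filter sharpness", {
  probe <- probe_config(1000, 30)
  lst <- listener_model(auditory_filter_q10 = 5)
  up <- simulate_listener_track(masker_config(1000, "up"), probe, lst,
                                seed = 5)
  down <- simulate_listener_track(masker_config(1000, "down"), probe, lst,
                                  seed = 1005)
  res <- analyze_ptc(up, down)
  expect_s3_class(res$ptc, "tuning_curve")
  expect_equal(res$ptc$kind, "PTC")
  expect_equal(q10(res$ptc), 5, tolerance = 0.15)
  # tip near the probe frequency and its masked-threshold level
  expect_equal(res$ptc$f_tip, 1000, tolerance = 0.02)
  expect_equal(res$ptc$L_tip, 45, tolerance = 0.05)
})
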