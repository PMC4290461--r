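#' Parametric virtual ear (SFOAE source model)
#'
#' Generative model of the ear-canal signal used to validate the whole SFOAE
#' pipeline against known ground truth. It combines: a compressive SFOAE
#' input/output function; sinusoidal fine structure of emission amplitude vs
#' probe frequency; two-tone suppression with a V-shaped iso-suppression
#' contour (rounded-exponential in log frequency) whose tip lies a fraction
#' `tip_shift_frac` above the probe frequency; a fixed emission latency;
#' additive Gaussian noise; and linear leak-through of both stimulus channels.
#'
#' @param cf characteristic (nominal test) frequency, Hz.
#' @param sfoae_gain_db SFOAE level re probe level in the linear regime, dB
#'   (default -20: a 30 dB SPL probe evokes roughly an 8 dB SPL emission after
#'   compression).
#' @param compression_knee_db probe level (dB SPL) where I/O growth starts to
#'   saturate.
#' @param compression_slope dB/dB growth well above the knee (< 1).
#' @param fine_structure_period_hz,fine_structure_depth_db sinusoidal ripple
#'   of emission level vs probe frequency.
#' @param fine_structure_peak_hz frequency of a ripple maximum; defaults to
#'   `1.05 * cf` so the best probe frequency sits slightly above the nominal CF.
#' @param filter_q10 sharpness (Q10) of the iso-50%-suppression contour.
#' @param tip_shift_frac tip position of the suppression filter relative to
#'   f_p: tip at `(1 + tip_shift_frac) * f_p` (default 0.12).
#' @param supp_l50_tip_db suppressor level (dB SPL) giving 50% suppression at
#'   the filter tip.
#' @param supp_slope_db logistic slope (dB) of suppression growth with level.
#' @param latency_ms SFOAE delay, ms (pure phase rotation at f_p).
#' @param noise_floor_db broadband RMS level of the additive acquisition
#'   noise, dB SPL (`-Inf` for noise-free).
#' @param artifact_gain linear gain of stimulus leak-through into the
#'   microphone.
#' @param suppressor_emission_gain_db level of the suppressor-evoked emission
#'   re the (compressed) suppressor response, dB.
#' @return An object of class `ear_model`.
#' @export
ear_model <- function(cf,
                      sfoae_gain_db = -20,
                      compression_knee_db = 30,
                      compression_slope = 0.3,
                      fine_structure_period_hz = 800,
                      fine_structure_depth_db = 6,
                      fine_structure_peak_hz = 1.05 * cf,
                      filter_q10 = 5,
                      tip_shift_frac = 0.12,
                      supp_l50_tip_db = 45,
                      supp_slope_db = 3,
                      latency_ms = 5,
                      noise_floor_db = 0,
                      artifact_gain = 1) {
  if (filter_q10 <= 0) stop_oaetune("filter_q10 must be > 0", "oaetune_bad_model")
  if (tip_shift_frac < 0 || tip_shift_frac >= 1)
    stop_oaetune("tip_shift_frac must lie in [0, 1)", "oaetune_bad_model")
  structure(
    list(cf = cf, sfoae_gain_db = sfoae_gain_db,
         compression_knee_db = compression_knee_db,
         compression_slope = compression_slope,
         fine_structure_period_hz = fine_structure_period_hz,
         fine_structure_depth_db = fine_structure_depth_db,
         fine_structure_peak_hz = fine_structure_peak_hz,
         filter_q10 = filter_q10, tip_shift_frac = tip_shift_frac,
         supp_l50_tip_db = supp_l50_tip_db, supp_slope_db = supp_slope_db,
         latency_ms = latency_ms, noise_floor_db = noise_floor_db,
         artifact_gain = artifact_gain,
         suppressor_emission_gain_db = -25),
    class = "ear_model"
  )
}

#' @export
print.ear_model <- function(x, ...) {
  cat(sprintf(
    "<ear_model> CF %g Hz | filter Q10 %.2f, tip at %.3f*f_p | knee %g dB, slope %.2f | noise %g dB SPL\n",
    x$cf, x$filter_q10, 1 + x$tip_shift_frac, x$compression_knee_db,
    x$compression_slope, x$noise_floor_db))
  invisible(x)
}

#' SFOAE level as a function of probe level (compressive I/O)
#'
#' Linear (1 dB/dB) growth well below the compression knee, bending smoothly
#' to `compression_slope` dB/dB above it; strictly increasing everywhere.
#'
#' @param ear an [ear_model()].
#' @param L_p probe level(s), dB SPL.
#' @param f_p probe frequency, Hz; adds the fine-structure ripple (omit or set
#'   `NULL` for the ripple-free backbone).
#' @return SFOAE level(s), dB SPL.
#' @export
sfoae_io_level <- function(ear, L_p, f_p = NULL) {
  stopifnot(inherits(ear, "ear_model"))
  out <- ear$sfoae_gain_db + L_p -
    (1 - ear$compression_slope) * softplus(L_p - ear$compression_knee_db, 4)
  if (!is.null(f_p)) {
    out <- out + ear$fine_structure_depth_db *
      cos(2 * pi * (f_p - ear$fine_structure_peak_hz) / ear$fine_structure_period_hz)
  }
  out
}

#' Two-tone suppression fraction of the virtual ear
#'
#' Fraction of the probe-evoked SFOAE removed by a suppressor at (`f_s`,
#' `L_s`). Logistic in suppressor level around a V-shaped 50%-suppression
#' contour: `L50(f_s) = supp_l50_tip_db + atten(f_s)`, where the attenuation
#' is a rounded-exponential in log2 frequency centred at
#' `(1 + tip_shift_frac) * f_p` with sharpness `filter_q10`. Monotone
#' non-decreasing in `L_s`, with limits 0 (`L_s -> -Inf`) and 1
#' (`L_s -> Inf`).
#'
#' @param ear an [ear_model()].
#' @param f_s,L_s suppressor frequency (Hz) and level (dB SPL).
#' @param f_p,L_p probe frequency (Hz) and level (dB SPL).
#' @return Suppression fraction in `[0, 1]`.
#' @export
suppression_fraction <- function(ear, f_s, L_s, f_p, L_p = 30) {
  stopifnot(inherits(ear, "ear_model"))
  l50 <- suppression_l50(ear, f_s, f_p)
  stats::plogis((L_s - l50) / ear$supp_slope_db)
}

# the model's iso-50%-suppression level at f_s (the ground-truth STC shape)
suppression_l50 <- function(ear, f_s, f_p) {
  tip <- (1 + ear$tip_shift_frac) * f_p
  ear$supp_l50_tip_db + roex_atten_db(f_s, tip, ear$filter_q10)
}

#' Simulate one four-buffer SFOAE acquisition
#'
#' Produces the four stored ear-canal buffers A-D for a six-section stimulus:
#' each buffer holds the stimulus leak-through (`artifact_gain` times probe +
#' suppressor section), the emission components of the model, and fresh
#' Gaussian noise. A and B carry the full probe-evoked emission; C and D carry
#' the suppressed emission plus the suppressor-evoked emission with the
#' suppressor's polarity (+ in C, - in D). `n_averages` independent
#' acquisitions are averaged sample-wise.
#'
#' @param stim a `buffered_stimulus` from [synth_sfoae_paradigm()].
#' @param ear an [ear_model()].
#' @param n_averages number of sub-averages (default 64).
#' @param seed RNG seed for the acquisition noise.
#' @return A [buffer_set()].
#' @export
simulate_sfoae_acquisition <- function(stim, ear, n_averages = 64,
                                       seed = NULL) {
  stopifnot(inherits(stim, "buffered_stimulus"), inherits(ear, "ear_model"))
  sr <- stim$sample_rate
  n_w <- round(stim$T_w * sr)
  f_p <- stim$f_p; L_p <- stim$L_p; f_s <- stim$f_s; L_s <- stim$L_s

  # probe-evoked emission (same in every section: probe is continuous)
  sfe_db <- sfoae_io_level(ear, L_p, f_p)
  sfe_amp <- amp_from_db_spl(sfe_db)
  frac <- if (is.finite(L_s)) suppression_fraction(ear, f_s, L_s, f_p, L_p) else 0
  lat <- ear$latency_ms / 1000

  sections <- c("A", "B", "C", "D")
  starts <- stim$section_boundaries[sections]
  # start phases via integer modular arithmetic: congruent sections get
  # bitwise-identical emission waveforms
  phase0 <- 2 * pi * (tone_phase_frac(starts - 1, f_p, sr) - f_p * lat)
  tt <- (seq_len(n_w) - 1) / sr
  buf <- vector("list", 4); names(buf) <- sections
  for (k in seq_along(sections)) {
    sec <- stimulus_section(stim, sections[k])
    x <- ear$artifact_gain * (sec[, 1] + sec[, 2])
    amp_k <- if (sections[k] %in% c("A", "B")) sfe_amp else sfe_amp * (1 - frac)
    x <- x + amp_k * sin(2 * pi * f_p * tt + phase0[k])
    if (is.finite(L_s) && sections[k] %in% c("C", "D")) {
      # suppressor-evoked emission: same buffer-local waveform in C and D,
      # with the suppressor's polarity (+C, -D), so (C + D) cancels it
      sfes_db <- sfoae_io_level(ear, L_s) + ear$suppressor_emission_gain_db
      sgn <- if (sections[k] == "C") 1 else -1
      x <- x + sgn * amp_from_db_spl(sfes_db) *
        sin(2 * pi * f_s * (tt - lat))
    }
    buf[[k]] <- x
  }
  if (is.finite(ear$noise_floor_db)) {
    sd_n <- rms_from_db_spl(ear$noise_floor_db)
    buf <- with_seed(seed, {
      lapply(buf, function(x) {
        noise <- matrix(rnorm(n_w * n_averages, sd = sd_n), nrow = n_w)
        x + rowMeans(noise)
      })
    })
  }
  buffer_set(buf$A, buf$B, buf$C, buf$D, sample_rate = sr,
             f_p = f_p, L_p = L_p, f_s = f_s, L_s = L_s,
             n_averages = n_averages)
}

#' Virtual listener for the fast PTC test
#'
#' A button-pressing listener whose masked detection follows a power-spectrum
#' masking rule: the probe is audible while the masker level, attenuated by a
#' rounded-exponential auditory filter centred at the probe frequency, stays
#' more than `threshold_snr_db` below the probe level. Responses are delayed
#' by `reaction_ms` plus Gaussian jitter.
#'
#' @param auditory_filter_q10 listener filter sharpness (Q10).
#' @param threshold_snr_db detection criterion: probe-minus-masker level in
#'   dB at the filter output at masked threshold (negative values mean the
#'   masker must exceed the probe inside the filter).
#' @param reaction_ms mean response latency, ms.
#' @param reaction_jitter_ms SD of the latency, ms.
#' @export
listener_model <- function(auditory_filter_q10 = 5, threshold_snr_db = -15,
                           reaction_ms = 300, reaction_jitter_ms = 50) {
  if (auditory_filter_q10 <= 0)
    stop_oaetune("auditory_filter_q10 must be > 0", "oaetune_bad_model")
  if (reaction_ms < 0)
    stop_oaetune("reaction_ms must be >= 0", "oaetune_bad_model")
  structure(
    list(auditory_filter_q10 = auditory_filter_q10,
         threshold_snr_db = threshold_snr_db,
         reaction_ms = reaction_ms, reaction_jitter_ms = reaction_jitter_ms),
    class = "listener_model"
  )
}

#' @export
print.listener_model <- function(x, ...) {
  cat(sprintf(
    "<listener_model> filter Q10 %.2f | criterion %g dB | reaction %g +/- %g ms\n",
    x$auditory_filter_q10, x$threshold_snr_db, x$reaction_ms,
    x$reaction_jitter_ms))
  invisible(x)
}

# masked threshold of the listener: masker level at f_c that just masks the
# probe (f_p, L_p); the ground-truth PTC shape
listener_masked_threshold <- function(listener, f_c, f_p, L_p) {
  L_p - listener$threshold_snr_db +
    roex_atten_db(f_c, f_p, listener$auditory_filter_q10)
}

#' Simulate a Bekesy-style masker tracking run
#'
#' The masker level rises at `rate_db_per_s` while the (delayed) listener
#' reports the probe audible and falls while it is inaudible, so the track
#' oscillates about the masked threshold as the masker centre frequency
#' sweeps. Press/release events are logged with
#' latency and jitter; levels are capped at `max_level_db`.
#'
#' @param masker_traj trajectory data.frame from [synth_masker_sweep()] (or a
#'   [masker_config()], from which the nominal trajectory is built); columns
#'   `segment`, `t_center_s`, `f_hz`.
#' @param probe a [probe_config()].
#' @param listener a [listener_model()].
#' @param rate_db_per_s level change rate (default 2 dB/s).
#' @param start_level_db initial masker level, dB SPL.
#' @param max_level_db level ceiling (90 dB SPL).
#' @param lead_in_s masker onset re probe onset (5 s).
#' @param dt simulation step, s.
#' @param seed RNG seed (reaction jitter).
#' @return A [tracking_record()].
#' @export
simulate_listener_track <- function(masker_traj, probe, listener,
                                    rate_db_per_s = 2, start_level_db = 40,
                                    max_level_db = 90, lead_in_s = 5,
                                    dt = 0.05, seed = NULL) {
  stopifnot(inherits(probe, "probe_config"), inherits(listener, "listener_model"))
  if (inherits(masker_traj, "masker_config")) {
    cfg <- masker_traj
    hop_s <- cfg$segment_ms / 1000 * (1 - cfg$overlap_frac)
    masker_traj <- data.frame(
      segment = seq_len(cfg$n_segments),
      t_center_s = (seq_len(cfg$n_segments) - 1) * hop_s + cfg$segment_ms / 2000,
      f_hz = cfg$f_i
    )
    sweep_dir <- cfg$sweep_dir
  } else {
    sweep_dir <- if (masker_traj$f_hz[nrow(masker_traj)] >= masker_traj$f_hz[1])
      "up" else "down"
  }
  # masker (trajectory) time runs from lead_in_s in probe time
  t_end <- max(masker_traj$t_center_s) +
    (masker_traj$t_center_s[2] - masker_traj$t_center_s[1]) / 2
  n_steps <- ceiling(t_end / dt)
  t_grid <- (seq_len(n_steps) - 1) * dt
  # piecewise-constant frequency: segment whose centre is nearest in time
  f_of_t <- approx(masker_traj$t_center_s, masker_traj$f_hz, xout = t_grid,
                   method = "constant", rule = 2, f = 0.5)$y
  thr <- listener_masked_threshold(listener, f_of_t, probe$f_p, probe$L_p)

  level <- numeric(n_steps)
  pressed_track <- logical(n_steps)
  level[1] <- min(start_level_db, max_level_db)
  events_t <- numeric(0); events_e <- character(0)
  with_seed(seed, {
    pressed <- TRUE # probe audible at masker onset
    pend_t <- Inf; pend_state <- NA
    for (k in seq_len(n_steps)) {
      if (k > 1) {
        dlev <- if (pressed) rate_db_per_s * dt else -rate_db_per_s * dt
        level[k] <- min(max_level_db, level[k - 1] + dlev)
      }
      audible <- level[k] < thr[k]
      # schedule a button flip when perceived audibility changes
      if (is.na(pend_state) || audible != pend_state) {
        if (audible != pressed) {
          jit <- if (listener$reaction_jitter_ms > 0)
            rnorm(1, sd = listener$reaction_jitter_ms / 1000) else 0
          pend_t <- t_grid[k] + max(0, listener$reaction_ms / 1000 + jit)
          pend_state <- audible
        } else {
          pend_t <- Inf; pend_state <- NA
        }
      }
      if (!is.na(pend_state) && t_grid[k] >= pend_t) {
        pressed <- pend_state
        events_t <- c(events_t, t_grid[k] + lead_in_s)
        events_e <- c(events_e, if (pressed) "press" else "release")
        pend_t <- Inf; pend_state <- NA
      }
      pressed_track[k] <- pressed
    }
  })
  tracking_record(
    events = data.frame(time_s = events_t, event = events_e,
                        stringsAsFactors = FALSE),
    level_traj = data.frame(time_s = t_grid + lead_in_s, level_db = level),
    freq_traj = data.frame(time_s = masker_traj$t_center_s + lead_in_s,
                           segment = masker_traj$segment,
                           f_hz = masker_traj$f_hz),
    sweep_dir = sweep_dir, f_p = probe$f_p, L_p = probe$L_p,
    lead_in_s = lead_in_s
  )
}
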