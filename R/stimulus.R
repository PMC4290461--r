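#' Probe-train configuration for the fast PTC test
#'
#' The behavioral probe is a pulsed pure tone: each 700-ms cycle is a 200-ms
#' silent interval followed by a 500-ms tone whose rise and decay are shaped by
#' a 20-ms raised-cosine gate. 350 cycles give the full 245-s presentation.
#'
#' @param f_p probe frequency in Hz.
#' @param L_p probe level in dB SPL (tone plateau RMS).
#' @param cycle_ms,gap_ms,tone_ms,ramp_ms cycle timing in ms; `cycle_ms` must
#'   equal `gap_ms + tone_ms`.
#' @param n_cycles number of probe cycles.
#' @export
probe_config <- function(f_p, L_p = 30, cycle_ms = 700, gap_ms = 200,
                         tone_ms = 500, ramp_ms = 20, n_cycles = 350) {
  if (cycle_ms != gap_ms + tone_ms)
    stop_oaetune("cycle_ms must equal gap_ms + tone_ms", "oaetune_bad_config")
  if (L_p <= -Inf || !is.finite(L_p))
    stop_oaetune("L_p must be finite", "oaetune_bad_config")
  structure(
    list(f_p = f_p, L_p = L_p, cycle_ms = cycle_ms, gap_ms = gap_ms,
         tone_ms = tone_ms, ramp_ms = ramp_ms, n_cycles = n_cycles),
    class = "probe_config"
  )
}

#' Masker-sweep configuration
#'
#' The fast-PTC masker is a 240-s narrowband noise whose centre frequency is
#' stepped geometrically by a factor 1.00185 per 640-ms segment across 750
#' segments (one octave either side of the probe), with adjacent segments
#' Hann-windowed and overlapped by 50%.
#'
#' @param f_p probe frequency (Hz); the sweep spans one octave either side.
#' @param sweep_dir `"up"` or `"down"`.
#' @param n_segments,segment_ms,overlap_frac,step_ratio segment plan.
#' @param max_level_db level ceiling in dB SPL; commanded levels above it are
#'   clipped (with a warning).
#' @return A `masker_config` with the per-segment centre frequencies `f_i` and
#'   the masker noise bandwidth (`0.2*f_p`, capped at 320 Hz).
#' @export
masker_config <- function(f_p, sweep_dir = c("up", "down"), n_segments = 750,
                          segment_ms = 640, overlap_frac = 0.5,
                          step_ratio = 1.00185, max_level_db = 90) {
  sweep_dir <- match.arg(sweep_dir)
  r <- if (sweep_dir == "up") step_ratio else 1 / step_ratio
  # ladder is centred on f_p in log frequency: f_1 * r^((n-1)/2) = f_p
  f_i <- f_p * r^(seq_len(n_segments) - 1 - (n_segments - 1) / 2)
  structure(
    list(f_p = f_p, sweep_dir = sweep_dir, n_segments = n_segments,
         segment_ms = segment_ms, overlap_frac = overlap_frac,
         step_ratio = step_ratio, max_level_db = max_level_db,
         f_i = f_i, bandwidth_hz = masker_bandwidth(f_p)),
    class = "masker_config"
  )
}

#' Masker noise bandwidth rule
#'
#' Bandwidth of the narrowband masker: 0.2 times the probe frequency, capped
#' at 320 Hz (a wide noise band broadens the PTC tip).
#' @param f_p probe frequency in Hz.
#' @export
masker_bandwidth <- function(f_p) min(0.2 * f_p, 320)

#' Suppressor configuration for the SFOAE paradigm
#'
#' @param f_s suppressor frequency in Hz.
#' @param L_s suppressor level in dB SPL. `-Inf` disables the suppressor.
#' @param ramp_ms rise/decay of the 5-ms raised-cosine gate.
#' @export
suppressor_config <- function(f_s, L_s = 70, ramp_ms = 5) {
  if (ramp_ms < 0) stop_oaetune("ramp_ms must be >= 0", "oaetune_bad_config")
  structure(list(f_s = f_s, L_s = L_s, ramp_ms = ramp_ms),
            class = "suppressor_config")
}

# raised-cosine (Hann-edge) on/off gate of length n samples with ramp_n ramps
cosine_gate <- function(n, ramp_n) {
  g <- rep(1, n)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    g[seq_len(ramp_n)] <- up
    g[n - ramp_n + seq_len(ramp_n)] <- rev(up)
  }
  g
}

#' Synthesize the pulsed probe train
#'
#' @param cfg a [probe_config()].
#' @param sample_rate sampling rate in Hz; `cfg$f_p` must be below Nyquist.
#' @return An [audio_signal()] of `n_cycles * cycle_ms` total duration.
#' @export
synth_probe_train <- function(cfg, sample_rate = 48000) {
  stopifnot(inherits(cfg, "probe_config"))
  if (cfg$f_p >= sample_rate / 2)
    stop_oaetune("probe frequency at or above Nyquist", "oaetune_aliasing")
  n_gap <- round(cfg$gap_ms / 1000 * sample_rate)
  n_tone <- round(cfg$tone_ms / 1000 * sample_rate)
  n_ramp <- round(cfg$ramp_ms / 1000 * sample_rate)
  amp <- amp_from_db_spl(cfg$L_p)
  t_tone <- (seq_len(n_tone) - 1) / sample_rate
  tone <- amp * sin(2 * pi * cfg$f_p * t_tone) * cosine_gate(n_tone, n_ramp)
  cycle <- c(numeric(n_gap), tone)
  audio_signal(rep(cycle, cfg$n_cycles), sample_rate)
}

#' Synthesize one narrowband noise segment
#'
#' A low-pass Gaussian noise of bandwidth `bandwidth/2` is built in the
#' frequency domain, inverse-transformed, and modulated by a sine at the
#' centre frequency, concentrating the spectrum in
#' `f_center +/- bandwidth/2`; the result is RMS-normalized to `level_db`.
#'
#' @param f_center centre frequency (Hz).
#' @param bandwidth noise bandwidth (Hz); the band must lie inside (0, Nyquist).
#' @param duration segment duration (s).
#' @param sample_rate sampling rate (Hz).
#' @param level_db target RMS level, dB SPL.
#' @param seed RNG seed for reproducible noise (optional).
#' @return An [audio_signal()].
#' @export
synth_narrowband_segment <- function(f_center, bandwidth, duration,
                                     sample_rate = 48000, level_db = 60,
                                     seed = NULL) {
  if (bandwidth <= 0)
    stop_oaetune("bandwidth must be > 0", "oaetune_bad_config")
  if (f_center - bandwidth / 2 <= 0 || f_center + bandwidth / 2 >= sample_rate / 2)
    stop_oaetune("noise band outside (0, Nyquist)", "oaetune_aliasing")
  n <- round(duration * sample_rate)
  df <- sample_rate / n
  k_max <- max(0L, floor((bandwidth / 2) / df)) # low-pass bins 0..k_max
  lp <- with_seed(seed, {
    spec <- complex(real = 0, imaginary = 0, length.out = n)
    z <- complex(real = rnorm(k_max + 1L), imaginary = rnorm(k_max + 1L))
    z[1] <- complex(real = Re(z[1]), imaginary = 0) # DC real
    spec[seq_len(k_max + 1L)] <- z
    if (k_max >= 1L) spec[n + 1L - seq_len(k_max)] <- Conj(z[1L + seq_len(k_max)])
    Re(fft(spec, inverse = TRUE)) / n
  })
  t <- (seq_len(n) - 1) / sample_rate
  x <- lp * sin(2 * pi * f_center * t)
  x <- x / rms(x) * rms_from_db_spl(level_db)
  audio_signal(x, sample_rate)
}

#' Synthesize the swept narrowband masker by overlap-add
#'
#' Each 640-ms segment is a narrowband noise at its ladder frequency `f_i`,
#' shaped by a Hann window `0.5*(1 - cos(2*pi*t/T))` and overlap-added at 50%
#' (Hann windows at exactly half overlap sum to a constant envelope). Segment
#' levels follow `level_track`; per-segment noise RMS is scaled by
#' `1/sqrt(0.75)` so the long-term overlap-added power matches the commanded
#' level.
#'
#' @param cfg a [masker_config()].
#' @param level_track dB SPL per segment: a scalar (constant) or a vector of
#'   length `n_segments`. Levels above `cfg$max_level_db` are clipped with a
#'   warning.
#' @param sample_rate sampling rate (Hz).
#' @param seed RNG seed; each segment draws fresh noise.
#' @return A list with `signal` (an [audio_signal()]) and `trajectory`, a
#'   data.frame (`segment`, `t_center_s`, `f_hz`, `level_db`) mapping time to
#'   masker frequency and level.
#' @export
synth_masker_sweep <- function(cfg, level_track, sample_rate = 48000,
                               seed = NULL) {
  stopifnot(inherits(cfg, "masker_config"))
  lev <- rep_len(level_track, cfg$n_segments)
  if (any(lev > cfg$max_level_db)) {
    warning(sprintf("clipping %d segment level(s) to %g dB SPL ceiling",
                    sum(lev > cfg$max_level_db), cfg$max_level_db))
    lev <- pmin(lev, cfg$max_level_db)
  }
  n_seg <- round(cfg$segment_ms / 1000 * sample_rate)
  hop <- round(n_seg * (1 - cfg$overlap_frac))
  n_tot <- (cfg$n_segments - 1) * hop + n_seg
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n_seg) - 1) / n_seg))
  out <- numeric(n_tot)
  with_seed(seed, {
    for (i in seq_len(cfg$n_segments)) {
      seg <- synth_narrowband_segment(
        cfg$f_i[i], cfg$bandwidth_hz, cfg$segment_ms / 1000, sample_rate,
        level_db = lev[i]
      )$samples
      # 1/sqrt(0.75): average of the squared 50%-overlapped Hann pair
      idx <- (i - 1) * hop + seq_len(n_seg)
      out[idx] <- out[idx] + seg / sqrt(0.75) * hann
    }
  })
  traj <- data.frame(
    segment = seq_len(cfg$n_segments),
    t_center_s = ((seq_len(cfg$n_segments) - 1) * hop + n_seg / 2) / sample_rate,
    f_hz = cfg$f_i,
    level_db = lev
  )
  list(signal = audio_signal(out, sample_rate), trajectory = traj)
}

#' Synthesize the six-section SFOAE probe/suppressor paradigm
#'
#' The stimulus has six sections: a lead-in M of duration `2*T_d` (absorbing
#' the system delay), then N, A, B, C, D of duration `T_w` each. The probe is
#' a continuous tone of constant polarity throughout. The suppressor is silent
#' except in sections C and D: a 5-ms raised-cosine gated tone burst in C and
#' its exact sample-wise negation in D (the final 5 ms of each burst is the
#' decay ramp).
#'
#' @param f_p,L_p probe frequency (Hz) and level (dB SPL).
#' @param supp a [suppressor_config()]; `L_s = -Inf` leaves the suppressor
#'   channel silent.
#' @param T_d system delay in s (default 0.0145).
#' @param T_w section duration in s (default 0.050).
#' @param sample_rate sampling rate (Hz).
#' @return A `buffered_stimulus`: two-channel [audio_signal()] (`probe`,
#'   `suppressor` columns) plus `section_boundaries` (named start indices of
#'   M, N, A, B, C, D), `T_d`, `T_w`, `f_p`, `L_p`, `f_s`, `L_s`.
#' @export
synth_sfoae_paradigm <- function(f_p, L_p, supp, T_d = 0.0145, T_w = 0.050,
                                 sample_rate = 48000) {
  stopifnot(inherits(supp, "suppressor_config"))
  if (T_d <= 0 || T_w <= 0)
    stop_oaetune("T_d and T_w must be > 0", "oaetune_bad_config")
  if (f_p >= sample_rate / 2 || supp$f_s >= sample_rate / 2)
    stop_oaetune("frequency at or above Nyquist", "oaetune_aliasing")
  n_ramp <- round(supp$ramp_ms / 1000 * sample_rate)
  n_w <- round(T_w * sample_rate)
  if (n_w < 2 * n_ramp)
    stop_oaetune("section shorter than the suppressor ramps", "oaetune_bad_config")
  n_d <- round(2 * T_d * sample_rate)
  n_tot <- n_d + 5 * n_w
  starts <- c(M = 1L, N = n_d + 1L, A = n_d + n_w + 1L, B = n_d + 2L * n_w + 1L,
              C = n_d + 3L * n_w + 1L, D = n_d + 4L * n_w + 1L)
  # build the probe section-wise with the start phase reduced by integer
  # modular arithmetic: sections with congruent phase get bitwise-identical
  # samples (so with no suppressor and no noise, buffers A-D are equal
  # exactly, not just to rounding)
  lens <- c(n_d, rep(n_w, 5))
  amp_p <- amp_from_db_spl(L_p)
  probe <- unlist(lapply(seq_along(starts), function(k) {
    amp_p * sin(2 * pi * (tone_phase_frac(starts[k] - 1L, f_p, sample_rate) +
                            f_p * (seq_len(lens[k]) - 1) / sample_rate))
  }), use.names = FALSE)
  suppressor <- numeric(n_tot)
  if (is.finite(supp$L_s)) {
    idx_c <- starts[["C"]] - 1L + seq_len(n_w)
    burst <- amp_from_db_spl(supp$L_s) *
      sin(2 * pi * supp$f_s * (seq_len(n_w) - 1) / sample_rate) *
      cosine_gate(n_w, n_ramp)
    suppressor[idx_c] <- burst
    suppressor[starts[["D"]] - 1L + seq_len(n_w)] <- -burst
  }
  structure(
    list(
      signal = audio_signal(cbind(probe = probe, suppressor = suppressor),
                            sample_rate),
      section_boundaries = starts, T_d = T_d, T_w = T_w,
      f_p = f_p, L_p = L_p, f_s = supp$f_s, L_s = supp$L_s,
      sample_rate = sample_rate
    ),
    class = "buffered_stimulus"
  )
}

# fractional start phase (cycles) of a tone of frequency f at sample n0,
# computed with exact integer arithmetic so congruent sections agree bitwise
tone_phase_frac <- function(n0, f, sample_rate) {
  ((n0 * f) %% sample_rate) / sample_rate
}

# pull one named section (both channels) out of a buffered_stimulus
stimulus_section <- function(stim, name) {
  n_w <- round(stim$T_w * stim$sample_rate)
  i0 <- stim$section_boundaries[[name]]
  stim$signal$samples[i0 - 1L + seq_len(n_w), , drop = FALSE]
}
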