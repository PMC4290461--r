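#' Four-buffer SFOAE acquisition
#'
#' The ear-canal signals recorded during stimulus sections A-D of the
#' six-section paradigm: A and B carry probe artifact and full emission; C
#' carries probe artifact, +suppressor artifact, +suppressor-evoked emission
#' and the suppressed emission; D the same with the suppressor components
#' negated.
#'
#' @param A,B,C,D numeric vectors of equal length (pressure, Pa).
#' @param sample_rate sampling rate, Hz.
#' @param f_p,L_p probe frequency (Hz) and level (dB SPL).
#' @param f_s,L_s suppressor frequency (Hz) and level (dB SPL).
#' @param n_averages number of sub-averages already folded into the buffers.
#' @export
buffer_set <- function(A, B, C, D, sample_rate, f_p, L_p,
                       f_s = NA_real_, L_s = NA_real_, n_averages = 64) {
  lens <- c(length(A), length(B), length(C), length(D))
  if (length(unique(lens)) != 1)
    stop_oaetune("buffers A-D must have equal length", "oaetune_bad_buffers")
  if (n_averages < 1)
    stop_oaetune("n_averages must be >= 1", "oaetune_bad_buffers")
  structure(
    list(A = A, B = B, C = C, D = D, sample_rate = sample_rate,
         f_p = f_p, L_p = L_p, f_s = f_s, L_s = L_s, n_averages = n_averages),
    class = "buffer_set"
  )
}

# zero-phase Butterworth high-pass: forward-backward 4th order, with
# reflection padding to suppress the filter's edge transients
zero_phase_highpass <- function(x, sample_rate, cutoff_hz = 500, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "high")
  n_pad <- min(length(x) - 1L, 3L * round(sample_rate / cutoff_hz) * order)
  xp <- c(2 * x[1] - x[n_pad + 1 - seq_len(n_pad) + 1],
          x,
          2 * x[length(x)] - x[length(x) - seq_len(n_pad)])
  yp <- signal::filtfilt(bf, xp)
  yp[n_pad + seq_along(x)]
}

#' Extract the suppressed SFOAE residual from a four-buffer acquisition
#'
#' Computes the residual `[(A + B) - (C + D)] / 2` in the time domain, which
#' cancels the probe artifact, the suppressor artifact and the
#' suppressor-evoked emission exactly, leaving `SFE - SFE'` (the amount of
#' probe-evoked emission removed by the suppressor; with full suppression the
#' residual *is* the emission). The residual is passed through a zero-phase
#' high-pass filter (forward-backward Butterworth, cutoff 500 Hz), trimmed to
#' a whole number of probe periods, and Fourier-transformed; amplitude and
#' phase are read at the FFT bin nearest `f_p`, and the noise floor is the
#' median amplitude of neighbouring bins.
#'
#' @param buffers a [buffer_set()].
#' @param highpass_hz high-pass cutoff, Hz (default 500; `0` disables).
#' @return An `sfoae_result` with `amplitude_db_spl` (RMS dB SPL of the
#'   residual component at f_p), `phase_rad`, `frequency`, `noise_floor_db`,
#'   `n_averages`.
#' @export
extract_residual <- function(buffers, highpass_hz = 500) {
  stopifnot(inherits(buffers, "buffer_set"))
  sr <- buffers$sample_rate
  f_p <- buffers$f_p
  r <- ((buffers$A + buffers$B) - (buffers$C + buffers$D)) / 2
  if (highpass_hz > 0) r <- zero_phase_highpass(r, sr, highpass_hz)
  # trim to a whole number of probe periods to avoid spectral leakage
  n_per <- floor(length(r) * f_p / sr)
  if (n_per < 1)
    stop_oaetune("buffer shorter than one probe period", "oaetune_bad_buffers")
  n <- round(n_per * sr / f_p)
  r <- r[seq_len(n)]
  spec <- fft(r)
  k <- round(f_p / sr * n) # 0-based bin index
  if (k < 1 || k > floor(n / 2))
    stop_oaetune("f_p bin outside the spectrum", "oaetune_bad_buffers")
  comp_amp <- 2 * Mod(spec[k + 1]) / n # peak amplitude of the f_p component
  # noise floor: median amplitude over neighbouring bins (+/- 3..12 bins)
  nb <- c(k - (3:12), k + (3:12))
  nb <- nb[nb >= 1 & nb <= floor(n / 2)]
  noise_amp <- stats::median(2 * Mod(spec[nb + 1]) / n)
  structure(
    list(amplitude_db_spl = db_spl_from_rms(comp_amp / sqrt(2)),
         phase_rad = Arg(spec[k + 1]),
         frequency = f_p,
         noise_floor_db = db_spl_from_rms(noise_amp / sqrt(2)),
         n_averages = buffers$n_averages),
    class = "sfoae_result"
  )
}

#' @export
print.sfoae_result <- function(x, ...) {
  cat(sprintf("<sfoae_result> %.1f Hz: %.2f dB SPL (noise %.2f dB SPL, n=%d)\n",
              x$frequency, x$amplitude_db_spl, x$noise_floor_db, x$n_averages))
  invisible(x)
}

#' Acquisition closure backed by the virtual ear
#'
#' Builds the `acquire(f_p, L_p, f_s, L_s)` callable used by the SFOAE
#' pipeline functions: each call synthesizes the six-section paradigm and
#' simulates a four-buffer acquisition with the given ear model. Successive
#' calls use consecutive seeds derived from `seed`, so a pipeline run is
#' reproducible end to end.
#'
#' @param ear an [ear_model()].
#' @param sample_rate sampling rate, Hz.
#' @param n_averages sub-averages per acquisition (default 64).
#' @param seed base RNG seed (optional).
#' @param T_d,T_w paradigm timing, s.
#' @return A function `(f_p, L_p, f_s, L_s) -> buffer_set`.
#' @export
virtual_acquirer <- function(ear, sample_rate = 48000, n_averages = 64,
                             seed = NULL, T_d = 0.0145, T_w = 0.050) {
  stopifnot(inherits(ear, "ear_model"))
  counter <- 0L
  function(f_p, L_p, f_s, L_s) {
    counter <<- counter + 1L
    stim <- synth_sfoae_paradigm(f_p, L_p, suppressor_config(f_s, L_s),
                                 T_d = T_d, T_w = T_w,
                                 sample_rate = sample_rate)
    simulate_sfoae_acquisition(stim, ear, n_averages = n_averages,
                               seed = if (is.null(seed)) NULL else seed + counter)
  }
}

# the standard strong near-probe reference suppressor: f_p - 47 Hz, 70 dB SPL
REF_SUPPRESSOR_OFFSET_HZ <- 47
REF_SUPPRESSOR_LEVEL_DB <- 70

# measure the "total SFOAE" with the reference suppressor
measure_total_sfoae <- function(f_p, L_p, acquire) {
  extract_residual(acquire(f_p, L_p, f_p - REF_SUPPRESSOR_OFFSET_HZ,
                           REF_SUPPRESSOR_LEVEL_DB))
}

#' Measure SFOAE fine structure and pick the best probe frequency
#'
#' Records the SFOAE on an 11-point grid in 40-Hz steps spanning `cf +/- 200`
#' Hz (reference suppressor at `f_p - 47` Hz, 70 dB SPL) and returns the grid
#' with the best probe frequency, the argmax of emission amplitude (ties
#' broken toward `cf`).
#'
#' @param cf characteristic frequency, Hz.
#' @param acquire acquisition callable, e.g. from [virtual_acquirer()].
#' @param L_p probe level, dB SPL.
#' @param step_hz,span_hz grid step and half-span, Hz.
#' @return A `fine_structure` object: `frequencies`, `amplitudes` (dB SPL),
#'   `noise_floors`, `best_f_p` (NA, flagged, when every point is at or below
#'   the noise floor).
#' @export
run_fine_structure <- function(cf, acquire, L_p = 30, step_hz = 40,
                               span_hz = 200) {
  freqs <- seq(cf - span_hz, cf + span_hz, by = step_hz)
  res <- lapply(freqs, function(f) measure_total_sfoae(f, L_p, acquire))
  amps <- vapply(res, `[[`, numeric(1), "amplitude_db_spl")
  noise <- vapply(res, `[[`, numeric(1), "noise_floor_db")
  if (all(amps <= noise)) {
    best <- NA_real_
  } else {
    cand <- which(amps == max(amps))
    best <- freqs[cand[which.min(abs(freqs[cand] - cf))]]
  }
  structure(
    list(frequencies = freqs, amplitudes = amps, noise_floors = noise,
         best_f_p = best, cf = cf, L_p = L_p),
    class = "fine_structure"
  )
}

#' @export
print.fine_structure <- function(x, ...) {
  cat(sprintf("<fine_structure> CF %g Hz, %d points (%g-Hz steps): best f_p = %s Hz\n",
              x$cf, length(x$frequencies),
              diff(x$frequencies[1:2]),
              format(x$best_f_p)))
  invisible(x)
}

#' @export
plot.fine_structure <- function(x, ...) {
  graphics::plot(x$frequencies, x$amplitudes, type = "b", pch = 16,
                 xlab = "probe frequency (Hz)", ylab = "SFOAE level (dB SPL)",
                 main = "SFOAE fine structure", ...)
  graphics::lines(x$frequencies, x$noise_floors, lty = 3)
  if (is.finite(x$best_f_p))
    graphics::abline(v = x$best_f_p, col = 2, lty = 2)
  invisible(x)
}

#' Measure the SFOAE input/output function
#'
#' One residual extraction per probe level (reference suppressor), returning
#' the paired probe and emission levels.
#'
#' @param f_p probe frequency, Hz.
#' @param acquire acquisition callable.
#' @param levels probe levels, dB SPL (default 5-50 in 5-dB steps).
#' @return An `io_function` with `probe_levels` and `sfoae_levels`.
#' @export
run_io_function <- function(f_p, acquire, levels = seq(5, 50, by = 5)) {
  res <- lapply(levels, function(L) measure_total_sfoae(f_p, L, acquire))
  structure(
    list(probe_levels = levels,
         sfoae_levels = vapply(res, `[[`, numeric(1), "amplitude_db_spl"),
         noise_floors = vapply(res, `[[`, numeric(1), "noise_floor_db"),
         f_p = f_p),
    class = "io_function"
  )
}

#' @export
plot.io_function <- function(x, ...) {
  graphics::plot(x$probe_levels, x$sfoae_levels, type = "b", pch = 16,
                 xlab = "probe level (dB SPL)", ylab = "SFOAE level (dB SPL)",
                 main = sprintf("SFOAE I/O function at %g Hz", x$f_p), ...)
  graphics::lines(x$probe_levels, x$noise_floors, lty = 3)
  invisible(x)
}

#' Track the critical suppressor level at one suppressor frequency
#'
#' Finds, by bisection on `L_s` in `[l_lo, l_hi]`, the suppressor level at
#' which the residual is `criterion_db` (default -6 dB: half suppression) re
#' the total SFOAE. Returns `NA` -- a missing point, not an error -- when the
#' criterion cannot be reached even at `l_hi`.
#'
#' @param f_s suppressor frequency, Hz.
#' @param f_p,L_p probe frequency and level.
#' @param total_db total-SFOAE amplitude (dB SPL) measured with the reference
#'   suppressor.
#' @param acquire acquisition callable.
#' @param criterion_db suppression criterion in dB (default -6).
#' @param l_lo,l_hi bracket, dB SPL.
#' @param tol_db bisection tolerance, dB.
#' @return Critical level in dB SPL, or `NA` if unattainable.
#' @export
track_critical_level <- function(f_s, f_p, L_p, total_db, acquire,
                                 criterion_db = -6, l_lo = 0, l_hi = 90,
                                 tol_db = 0.5) {
  ratio_at <- function(L_s) {
    extract_residual(acquire(f_p, L_p, f_s, L_s))$amplitude_db_spl - total_db
  }
  if (ratio_at(l_hi) < criterion_db) return(NA_real_)
  if (ratio_at(l_lo) >= criterion_db) return(l_lo)
  lo <- l_lo; hi <- l_hi
  while (hi - lo > tol_db) {
    mid <- (lo + hi) / 2
    if (ratio_at(mid) >= criterion_db) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Build an SFOAE suppression tuning curve
#'
#' Measures the total SFOAE with the reference suppressor (`f_p - 47` Hz, 70
#' dB SPL), then tracks the critical suppressor level on a geometric grid of
#' suppressor frequencies (default `0.5*f_p` up to `f_hi_frac*f_p` at
#' `points_per_octave` points per octave: 2.5 for a CF of 1 kHz, 1.75 for 2
#' and 4 kHz). Missing points are kept as `NA` gaps. The tip is the curve
#' minimum.
#'
#' @param f_p,L_p probe frequency (Hz) and level (dB SPL).
#' @param acquire acquisition callable.
#' @param f_lo_frac,f_hi_frac suppressor range as fractions of `f_p`.
#' @param points_per_octave grid resolution (default 10).
#' @param criterion_db suppression criterion (default -6 dB).
#' @param tol_db level-tracking tolerance, dB.
#' @return A [tuning_curve()] of kind `"STC"`; fewer than 3 valid points is an
#'   error (curve rejected).
#' @export
build_stc <- function(f_p, acquire, L_p = 30, f_lo_frac = 0.5,
                      f_hi_frac = 2.5, points_per_octave = 10,
                      criterion_db = -6, tol_db = 0.5) {
  n_oct <- log2(f_hi_frac / f_lo_frac)
  k <- 0:floor(n_oct * points_per_octave)
  freqs <- f_p * f_lo_frac * 2^(k / points_per_octave)
  total <- measure_total_sfoae(f_p, L_p, acquire)
  levels <- vapply(freqs, function(f_s) {
    track_critical_level(f_s, f_p, L_p, total$amplitude_db_spl, acquire,
                         criterion_db = criterion_db, tol_db = tol_db)
  }, numeric(1))
  if (sum(is.finite(levels)) < 3)
    stop_oaetune("fewer than 3 valid STC points; curve rejected",
                 "oaetune_curve_rejected")
  tuning_curve(freqs, levels, kind = "STC", f_p = f_p, L_p = L_p,
               criterion_db = criterion_db)
}
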