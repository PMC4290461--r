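#' Bekesy tracking record
#'
#' Timestamped button press/release events from a fast-PTC run, together with
#' the masker's level trajectory (dense time grid) and frequency trajectory
#' (one centre frequency per 640-ms segment). Times are in probe time; the
#' masker starts `lead_in_s` (5 s) after the probe.
#'
#' @param events data.frame `time_s`, `event` (`"press"`/`"release"`),
#'   time-ordered and alternating.
#' @param level_traj data.frame `time_s`, `level_db`.
#' @param freq_traj data.frame `time_s` (segment centres), `segment`, `f_hz`.
#' @param sweep_dir `"up"` or `"down"`.
#' @param f_p,L_p probe frequency and level.
#' @param lead_in_s masker onset re probe onset, s.
#' @export
tracking_record <- function(events, level_traj, freq_traj,
                            sweep_dir = c("up", "down"), f_p, L_p,
                            lead_in_s = 5) {
  sweep_dir <- match.arg(sweep_dir)
  if (nrow(events) > 0) {
    if (is.unsorted(events$time_s))
      stop_oaetune("events must be time-ordered", "oaetune_bad_record")
    if (any(events$event[-1] == events$event[-nrow(events)]))
      stop_oaetune("events must alternate press/release", "oaetune_bad_record")
  }
  structure(
    list(events = events, level_traj = level_traj, freq_traj = freq_traj,
         sweep_dir = sweep_dir, f_p = f_p, L_p = L_p, lead_in_s = lead_in_s),
    class = "tracking_record"
  )
}

#' @export
print.tracking_record <- function(x, ...) {
  cat(sprintf(
    "<tracking_record:%s> %d events over %.0f s | %d segments | f_p %.0f Hz, L_p %g dB\n",
    x$sweep_dir, nrow(x$events), diff(range(x$level_traj$time_s)),
    nrow(x$freq_traj), x$f_p, x$L_p))
  invisible(x)
}

#' Raw jagged masker-level curve from a tracking record
#'
#' Samples the tracked masker level at each segment's centre frequency (level
#' commanded at the segment's temporal centre); samples in the 5-s lead-in
#' before masker onset are excluded.
#'
#' @param track a [tracking_record()].
#' @return A `raw_curve`: `frequencies` (per segment, monotone in the sweep
#'   direction), `levels` (dB SPL), plus the sweep metadata.
#' @export
record_to_raw <- function(track) {
  stopifnot(inherits(track, "tracking_record"))
  if (nrow(track$events) == 0)
    stop_oaetune("tracking record has no events", "oaetune_bad_record")
  ft <- track$freq_traj
  keep <- ft$time_s >= track$lead_in_s
  ft <- ft[keep, , drop = FALSE]
  lev <- approx(track$level_traj$time_s, track$level_traj$level_db,
                xout = ft$time_s, rule = 2)$y
  structure(
    list(frequencies = ft$f_hz, levels = lev, sweep_dir = track$sweep_dir,
         f_p = track$f_p, L_p = track$L_p),
    class = "raw_curve"
  )
}

#' Two-point average smoothing of a raw Bekesy curve
#'
#' Turning points of the jagged track are the points where the convolution of
#' the levels with the operator `[1, -2, 1]` is non-zero (|second difference|
#' greater than `eps`); the first and last points are always included. The
#' smoothed curve is the sequence of midpoints (in frequency and in level) of
#' each pair of adjacent turning points.
#'
#' @param raw a `raw_curve` (or any list with `frequencies` and `levels`).
#' @param eps threshold defining "non-zero" after convolution (default 1e-9
#'   dB, guarding against floating-point plateaus).
#' @return A `smoothed_curve` with `frequencies`, `levels`, and `degenerate =
#'   TRUE` (flag) when fewer than 2 interior turning points exist, in which
#'   case the raw curve is returned unchanged.
#' @export
smooth_raw <- function(raw, eps = 1e-9) {
  f <- raw$frequencies; l <- raw$levels
  n <- length(l)
  if (n < 3)
    stop_oaetune("need at least 3 points to smooth", "oaetune_bad_curve")
  d2 <- l[1:(n - 2)] - 2 * l[2:(n - 1)] + l[3:n] # 'same' alignment, interior
  interior <- 1 + which(abs(d2) > eps)
  turn <- unique(c(1L, interior, n))
  degenerate <- length(interior) < 2
  if (degenerate) {
    out <- list(frequencies = f, levels = l, turning_points = turn,
                degenerate = TRUE, sweep_dir = raw$sweep_dir,
                f_p = raw$f_p, L_p = raw$L_p)
  } else {
    i <- turn[-length(turn)]; j <- turn[-1]
    out <- list(frequencies = (f[i] + f[j]) / 2, levels = (l[i] + l[j]) / 2,
                turning_points = turn, degenerate = FALSE,
                sweep_dir = raw$sweep_dir, f_p = raw$f_p, L_p = raw$L_p)
  }
  structure(out, class = "smoothed_curve")
}

#' Tip of a smoothed curve
#'
#' The tip is the global minimum of the smoothed level; tied minima are
#' resolved to the geometric mean of the tied frequencies. A flat (all-equal)
#' curve has no tip and is flagged with an error.
#'
#' @param smoothed a `smoothed_curve` from [smooth_raw()].
#' @return A list `f_tip`, `L_tip`.
#' @export
estimate_tip <- function(smoothed) {
  tip <- curve_tip(smoothed$frequencies, smoothed$levels)
  if (!is.finite(tip$f_tip))
    stop_oaetune("curve has no tip (flat or empty levels)", "oaetune_no_tip")
  tip
}

#' Average upward and downward sweep PTCs
#'
#' Each sweep's frequency axis is normalized by its own tip frequency, the
#' two level curves are linearly interpolated onto a common grid (10 points
#' per octave in normalized log2 frequency over the overlap region) and
#' averaged, and the result is rescaled so the averaged tip maps to the
#' geometric mean of the two tip frequencies.
#'
#' @param up_smoothed,down_smoothed `smoothed_curve`s for the upward and
#'   downward sweeps.
#' @param points_per_octave resolution of the common normalized grid.
#' @return A [tuning_curve()] of kind `"PTC"`.
#' @export
average_sweeps <- function(up_smoothed, down_smoothed,
                           points_per_octave = 10) {
  tip_u <- estimate_tip(up_smoothed)
  tip_d <- estimate_tip(down_smoothed)
  norm_curve <- function(s, tip) {
    o <- order(s$frequencies)
    list(g = log2(s$frequencies[o] / tip$f_tip), l = s$levels[o])
  }
  cu <- norm_curve(up_smoothed, tip_u)
  cd <- norm_curve(down_smoothed, tip_d)
  g_lo <- max(min(cu$g), min(cd$g))
  g_hi <- min(max(cu$g), max(cd$g))
  if (g_lo >= g_hi)
    stop_oaetune("sweeps do not overlap after tip normalization",
                 "oaetune_bad_curve")
  step <- 1 / points_per_octave
  grid <- seq(ceiling(g_lo / step) * step, floor(g_hi / step) * step,
              by = step)
  lu <- approx(cu$g, cu$l, xout = grid)$y
  ld <- approx(cd$g, cd$l, xout = grid)$y
  lev <- (lu + ld) / 2
  f_tip_avg <- sqrt(tip_u$f_tip * tip_d$f_tip)
  # rescale so the averaged tip sits at the geometric-mean tip frequency
  g_min <- grid[which.min(lev)]
  freqs <- 2^(grid - g_min) * f_tip_avg
  tuning_curve(freqs, lev, kind = "PTC",
               f_p = up_smoothed$f_p, L_p = up_smoothed$L_p)
}

#' Full PTC analysis of an up/down sweep pair
#'
#' Convenience wrapper: raw extraction, two-point smoothing and tip
#' estimation per sweep, then up/down averaging.
#'
#' @param track_up,track_down [tracking_record()]s for the two sweeps.
#' @return A list with the averaged [tuning_curve()] (`ptc`), the per-sweep
#'   smoothed curves and tips.
#' @export
analyze_ptc <- function(track_up, track_down) {
  su <- smooth_raw(record_to_raw(track_up))
  sd_ <- smooth_raw(record_to_raw(track_down))
  list(ptc = average_sweeps(su, sd_),
       up_smoothed = su, down_smoothed = sd_,
       up_tip = estimate_tip(su), down_tip = estimate_tip(sd_))
}
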