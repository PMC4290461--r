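#' Tuning curve (STC or PTC)
#'
#' A set of (frequency, level) pairs describing an iso-response contour: for
#' an STC the suppressor level that reduces the SFOAE by the criterion at
#' each suppressor frequency; for a PTC the masker level that just masks the
#' probe at each masker frequency. The tip is the curve minimum; tied minima
#' are placed at the geometric mean of the tied frequencies.
#'
#' @param frequencies strictly increasing frequencies, Hz.
#' @param levels levels, dB SPL; `NA` marks a missing (gap) point.
#' @param kind `"STC"` or `"PTC"`.
#' @param f_p,L_p probe frequency and level the curve refers to.
#' @param criterion_db suppression criterion for STCs (default -6), `NA` for
#'   PTCs.
#' @return A `tuning_curve` with tip annotations `f_tip`, `L_tip`.
#' @export
tuning_curve <- function(frequencies, levels, kind = c("STC", "PTC"),
                         f_p = NA_real_, L_p = NA_real_,
                         criterion_db = if (kind[1] == "STC") -6 else NA_real_) {
  kind <- match.arg(kind)
  if (length(frequencies) != length(levels))
    stop_oaetune("frequencies and levels must have equal length",
                 "oaetune_bad_curve")
  if (any(diff(frequencies) <= 0))
    stop_oaetune("frequencies must be strictly increasing", "oaetune_bad_curve")
  tip <- curve_tip(frequencies, levels)
  structure(
    list(frequencies = frequencies, levels = levels, kind = kind,
         f_p = f_p, L_p = L_p, criterion_db = criterion_db,
         f_tip = tip$f_tip, L_tip = tip$L_tip),
    class = "tuning_curve"
  )
}

# minimum of a sampled curve; ties -> geometric mean of tied frequencies
curve_tip <- function(freqs, levels) {
  ok <- is.finite(levels)
  if (!any(ok)) return(list(f_tip = NA_real_, L_tip = NA_real_))
  lmin <- min(levels[ok])
  if (all(levels[ok] == lmin) && sum(ok) > 1) {
    # all-equal levels: no tip
    return(list(f_tip = NA_real_, L_tip = lmin, flat = TRUE))
  }
  tied <- freqs[ok][levels[ok] == lmin]
  list(f_tip = exp(mean(log(tied))), L_tip = lmin)
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf(
    "<tuning_curve:%s> %d points, %.0f-%.0f Hz | tip %.1f Hz @ %.1f dB SPL | f_p %.0f Hz, L_p %g dB\n",
    x$kind, length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$f_tip, x$L_tip, x$f_p, x$L_p))
  invisible(x)
}

#' @export
summary.tuning_curve <- function(object, ...) {
  q <- tryCatch(q10(object), error = function(e) NA_real_)
  off <- tryCatch(offset_ratios(object), error = function(e)
    list(horizontal_pct = NA_real_, vertical_pct = NA_real_))
  out <- list(kind = object$kind, n_points = length(object$frequencies),
              n_missing = sum(!is.finite(object$levels)),
              f_tip = object$f_tip, L_tip = object$L_tip, q10 = q,
              horizontal_offset_pct = off$horizontal_pct,
              vertical_offset_pct = off$vertical_pct)
  class(out) <- "summary.tuning_curve"
  out
}

#' @export
print.summary.tuning_curve <- function(x, ...) {
  cat(sprintf("%s tuning curve: %d points (%d missing)\n", x$kind, x$n_points,
              x$n_missing))
  cat(sprintf("  tip: %.1f Hz at %.1f dB SPL\n", x$f_tip, x$L_tip))
  cat(sprintf("  Q10: %.2f | offsets: %+.1f%% (freq), %+.1f%% (level)\n",
              x$q10, x$horizontal_offset_pct, x$vertical_offset_pct))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    graphics::plot(x$frequencies, x$levels, type = "b", pch = 16, log = "x",
                   col = col,
                   xlab = "frequency (Hz)", ylab = "level (dB SPL)",
                   main = sprintf("%s (f_p = %.0f Hz, L_p = %g dB SPL)",
                                  x$kind, x$f_p, x$L_p), ...)
  } else {
    graphics::lines(x$frequencies, x$levels, type = "b", pch = 16, col = col, ...)
  }
  if (is.finite(x$f_tip))
    graphics::points(x$f_tip, x$L_tip, pch = 8, col = 2, cex = 1.4)
  if (is.finite(x$f_p) && is.finite(x$L_p))
    graphics::points(x$f_p, x$L_p, pch = 42, col = 4, cex = 2)
  invisible(x)
}

#' Convert a tuning curve to a data.frame
#' @param x a [tuning_curve()].
#' @param ... unused.
#' @export
as.data.frame.tuning_curve <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, level_db = x$levels)
}
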