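#' Sampled acoustic pressure waveform
#'
#' Container for all stimuli and (simulated) ear-canal recordings. Samples are
#' linear pressure in pascal; levels in dB SPL are referenced to 20 micropascal,
#' so the level of a steady segment is `20*log10(RMS / 20e-6)`.
#'
#' @param samples numeric vector (or n x 2 matrix for a two-channel
#'   probe/suppressor signal) of pressure samples in Pa.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `spl_ref` (20e-6 Pa).
#' @examples
#' t <- seq(0, 0.1, by = 1 / 48000)
#' s <- audio_signal(sin(2 * pi * 1000 * t) * sqrt(2) * 20e-6 * 10^(30 / 20), 48000)
#' level_db_spl(s) # ~30 dB SPL
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_oaetune("sample_rate must be a positive scalar", "oaetune_bad_signal")
  if (!all(is.finite(samples)))
    stop_oaetune("samples must be finite", "oaetune_bad_signal")
  structure(
    list(samples = samples, sample_rate = sample_rate, spl_ref = P_REF),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  n <- NROW(x$samples)
  nc <- NCOL(x$samples)
  cat(sprintf(
    "<audio_signal> %d samples%s @ %g Hz (%.3f s), %.1f dB SPL overall\n",
    n, if (nc > 1) sprintf(" x %d channels", nc) else "",
    x$sample_rate, n / x$sample_rate, level_db_spl(x)
  ))
  invisible(x)
}

#' Overall level of a signal in dB SPL
#'
#' @param x an `audio_signal` or numeric vector of pressures in Pa.
#' @return RMS level in dB SPL (re 20 uPa). Multi-channel input is pooled.
#' @export
level_db_spl <- function(x) {
  s <- if (inherits(x, "audio_signal")) x$samples else x
  db_spl_from_rms(rms(as.numeric(s)))
}

#' Duration of a signal in seconds
#' @param x an `audio_signal`.
#' @export
duration_s <- function(x) NROW(x$samples) / x$sample_rate

# ---- WAV I/O -----------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer (IEEE float32, or PCM16 on read).
# Pressure samples are stored as-is in float format; callers keep track of the
# Pa <-> full-scale convention (we write raw Pa values, which float WAV allows).

#' Write an `audio_signal` to a WAV file (IEEE float32)
#'
#' Mono or two-channel (probe/suppressor) signals are supported. Samples are
#' written verbatim as 32-bit floats, preserving the pascal scaling.
#'
#' @param x an `audio_signal`.
#' @param path output file path.
#' @export
wav_write <- function(x, path) {
  stopifnot(inherits(x, "audio_signal"))
  smp <- x$samples
  if (is.null(dim(smp))) smp <- matrix(smp, ncol = 1)
  n_chan <- ncol(smp)
  n <- nrow(smp)
  sr <- as.integer(round(x$sample_rate))
  data <- as.numeric(t(smp)) # interleaved
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_data <- 4L * n * n_chan
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + bytes_data), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L * n_chan), con, size = 4, endian = "little")
  writeBin(as.integer(4L * n_chan), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(bytes_data, con, size = 4, endian = "little")
  writeBin(data, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a WAV file into an `audio_signal`
#'
#' Accepts IEEE float32 (format 3) and PCM16 (format 1, rescaled to [-1, 1))
#' files, mono or stereo.
#'
#' @param path WAV file path.
#' @param channels if given, required channel count; a mismatch is an error.
#' @export
wav_read <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_oaetune("not a RIFF/WAVE file", "oaetune_bad_wav")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_oaetune("not a RIFF/WAVE file", "oaetune_bad_wav")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), n = sz)
      fmt <- list(
        format = readBin(fmt_raw[1:2], integer(), size = 2, endian = "little"),
        n_chan = readBin(fmt_raw[3:4], integer(), size = 2, endian = "little"),
        sr = readBin(fmt_raw[5:8], integer(), size = 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], integer(), size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = sz)
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_oaetune("WAV file missing fmt or data chunk", "oaetune_bad_wav")
  if (fmt$format == 3 && fmt$bits == 32) {
    vals <- readBin(data_raw, numeric(), n = length(data_raw) / 4, size = 4,
                    endian = "little")
  } else if (fmt$format == 1 && fmt$bits == 16) {
    vals <- readBin(data_raw, integer(), n = length(data_raw) / 2, size = 2,
                    signed = TRUE, endian = "little") / 32768
  } else {
    stop_oaetune(
      sprintf("unsupported WAV encoding (format %d, %d bit)", fmt$format, fmt$bits),
      "oaetune_bad_wav"
    )
  }
  if (!is.null(channels) && fmt$n_chan != channels)
    stop_oaetune(
      sprintf("expected %d channel(s), file has %d", channels, fmt$n_chan),
      "oaetune_bad_wav"
    )
  smp <- if (fmt$n_chan > 1) t(matrix(vals, nrow = fmt$n_chan)) else vals
  audio_signal(smp, fmt$sr)
}
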