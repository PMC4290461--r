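# shared builders for synthetic fixtures (all generated in code)

# noise-free virtual ear for deterministic pipeline checks
quiet_ear <- function(cf = 1000, ...) {
  ear_model(cf = cf, noise_floor_db = -Inf, ...)
}

# Build a four-buffer set directly from physical components, independent of
# the simulator: probe artifact identical in A-D, suppressor artifact and
# suppressor-evoked emission with +C/-D polarity, emission amplitude sfe_amp
# in A/B and sfe_prime_amp in C/D. Frequencies in Hz, amplitudes in Pa.
make_buffers <- function(f_p = 1000, sfe_amp = 0, sfe_prime_amp = sfe_amp,
                         artifact_amp = 0.1, artifact_phase = 0.3,
                         f_s = 1300, supp_amp = 0.5, supp_phase = 1.1,
                         sfes_amp = 0.01, noise_sd = 0, n_samples = 2400,
                         sample_rate = 48000, seed = NULL) {
  t <- (seq_len(n_samples) - 1) / sample_rate
  rp <- artifact_amp * sin(2 * pi * f_p * t + artifact_phase)
  rs <- supp_amp * sin(2 * pi * f_s * t + supp_phase)
  sfes <- sfes_amp * sin(2 * pi * f_s * t + 0.7)
  sfe <- sin(2 * pi * f_p * t - 0.5)
  noise <- function() if (noise_sd > 0) rnorm(n_samples, sd = noise_sd) else 0
  withr_seed <- function(expr) if (is.null(seed)) expr else {
    set.seed(seed); expr
  }
  withr_seed({
    buffer_set(
      A = rp + sfe_amp * sfe + noise(),
      B = rp + sfe_amp * sfe + noise(),
      C = rp + rs + sfes + sfe_prime_amp * sfe + noise(),
      D = rp - rs - sfes + sfe_prime_amp * sfe + noise(),
      sample_rate = sample_rate, f_p = f_p, L_p = 30, f_s = f_s, L_s = 70,
      n_averages = 1
    )
  })
}

# staircase triangle wave sampled per segment: linear ramps of `half` points
# between lo and hi, starting upward; frequencies geometric
make_triangle_raw <- function(n = 60, half = 5, lo = 40, hi = 44,
                              f0 = 800, ratio = 1.00185) {
  one_up <- seq(lo, hi, length.out = half + 1)
  one_down <- seq(hi, lo, length.out = half + 1)[-1]
  lev <- rep(c(one_up[-1], one_down), length.out = n)
  structure(
    list(frequencies = f0 * ratio^(seq_len(n) - 1), levels = lev,
         sweep_dir = "up", f_p = 1000, L_p = 30),
    class = "raw_curve"
  )
}
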