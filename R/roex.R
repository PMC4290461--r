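# Rounded-exponential (roex) filter machinery shared by the virtual ear's
# suppression filter and the virtual listener's auditory filter.
#
# The weight is defined in log2-frequency distance g from the filter centre:
#   w(g) = (1 + p|g|) * exp(-p|g|),  w(0) = 1.
# Attenuation in dB is -10*log10(w).  The slope parameter p is calibrated so
# that the -10 dB points of the weight sit exactly Q10 apart in the usual
# sense: Q10 = f_c / (f_hi - f_lo), with f_hi/lo = f_c * 2^(+/-g10).

# x solving (1 + x) exp(-x) = 0.1, i.e. the -10 dB point of a roex in units
# of p*|g|; solved once at load time.
.roex_x10 <- local({
  f <- function(x) (1 + x) * exp(-x) - 0.1
  uniroot(f, c(1, 10), tol = 1e-12)$root
})

# half-width in octaves of the -10 dB points of a symmetric-in-log2 filter
# with the given q10: bandwidth f_c*(2^g - 2^-g) = f_c/q10.
roex_g10 <- function(q10) asinh(1 / (2 * q10)) / log(2)

# slope parameter from q10
roex_p <- function(q10) {
  stopifnot(q10 > 0)
  .roex_x10 / roex_g10(q10)
}

# weight at log2-frequency offset g (vectorized)
roex_weight <- function(g, p) {
  x <- p * abs(g)
  (1 + x) * exp(-x)
}

# attenuation in dB (>= 0) at frequency f for a filter centred at f_c
roex_atten_db <- function(f, f_c, q10) {
  g <- log2(f / f_c)
  -10 * log10(roex_weight(g, roex_p(q10)))
}
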