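# internal helpers shared across modules

P_REF <- 20e-6 # reference pressure, Pa (0 dB SPL)

#' @keywords internal
#' @noRd
db_spl_from_rms <- function(rms_pa) 20 * log10(rms_pa / P_REF)

#' @keywords internal
#' @noRd
rms_from_db_spl <- function(level_db) P_REF * 10^(level_db / 20)

# peak amplitude of a sinusoid whose RMS corresponds to level_db
amp_from_db_spl <- function(level_db) sqrt(2) * rms_from_db_spl(level_db)

rms <- function(x) sqrt(mean(x^2))

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_oaetune <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oaetune_error")))
}

# smooth rectifier used by the compressive I/O model; width w in dB
softplus <- function(x, w) ifelse(x / w > 30, x, w * log1p(exp(x / w)))
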