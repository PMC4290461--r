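#' Configuration of a full dual-assessment run
#'
#' Bundles every parameter of an end-to-end experiment at one CF: probe
#' level, virtual ear and listener parameters, acquisition settings and
#' analysis options. The suppressor frequency range follows the CF: 0.5-2.5
#' times f_p at 1 kHz, 0.5-1.75 times f_p at 2 and 4 kHz.
#'
#' @param cf characteristic frequency, Hz (1000, 2000 or 4000 in the standard
#'   protocol; any positive value is accepted).
#' @param L_p probe level, dB SPL.
#' @param ear named list of [ear_model()] arguments (less `cf`).
#' @param listener named list of [listener_model()] arguments.
#' @param sample_rate sampling rate, Hz.
#' @param n_averages SFOAE sub-averages.
#' @param criterion_db STC suppression criterion.
#' @param points_per_octave STC grid resolution.
#' @param f_hi_frac upper suppressor-range limit re f_p; default 2.5 below
#'   1.5 kHz and 1.75 at or above.
#' @param aberrant_threshold Q10-ratio exclusion threshold.
#' @param seed base RNG seed for every stochastic stage.
#' @export
run_config <- function(cf, L_p = 30, ear = list(), listener = list(),
                       sample_rate = 48000, n_averages = 64,
                       criterion_db = -6, points_per_octave = 10,
                       f_hi_frac = if (cf < 1500) 2.5 else 1.75,
                       aberrant_threshold = 1.5, seed = 1) {
  if (is.null(seed))
    stop_oaetune("a seed is required for the stochastic stages",
                 "oaetune_bad_config")
  structure(
    list(cf = cf, L_p = L_p, ear = ear, listener = listener,
         sample_rate = sample_rate, n_averages = n_averages,
         criterion_db = criterion_db, points_per_octave = points_per_octave,
         f_hi_frac = f_hi_frac, aberrant_threshold = aberrant_threshold,
         seed = seed),
    class = "run_config"
  )
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full dual assessment on the virtual ear and listener
#'
#' Executes the complete protocol at one CF: SFOAE fine structure to find the
#' best probe frequency, the SFOAE I/O function, the STC at the suppression
#' criterion; then upward and downward fast-PTC tracking runs and their
#' average -- with the same f_p and L_p in both tests -- and finally the
#' tuning-curve metrics. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @return A `run_bundle`: `fine_structure`, `io_function`, `stc`, `ptc`
#'   (averaged [tuning_curve()]), `tracks` (up/down [tracking_record()]s),
#'   `metrics` (one-row data.frame with f_p, Q10s, offsets), and `provenance`
#'   (config, hash, seeds, package version, per-stage timing).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop_oaetune(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "oaetune_stage_failure")
    })
    list(value = val, log = list(stage = name, seed = cfg$seed,
                                 duration_s = proc.time()[["elapsed"]] - t0))
  }
  logs <- list()
  ear <- do.call(ear_model, c(list(cf = cfg$cf), cfg$ear))
  listener <- do.call(listener_model, cfg$listener)
  acq <- virtual_acquirer(ear, sample_rate = cfg$sample_rate,
                          n_averages = cfg$n_averages, seed = cfg$seed)

  st <- stage("fine_structure",
              run_fine_structure(cfg$cf, acq, L_p = cfg$L_p))
  logs <- c(logs, list(st$log)); fs <- st$value
  if (!is.finite(fs$best_f_p))
    stop_oaetune("stage 'fine_structure' failed: no best frequency",
                 "oaetune_stage_failure")
  f_p <- fs$best_f_p

  st <- stage("io_function", run_io_function(f_p, acq))
  logs <- c(logs, list(st$log)); iof <- st$value

  st <- stage("stc",
              build_stc(f_p, acq, L_p = cfg$L_p, f_hi_frac = cfg$f_hi_frac,
                        points_per_octave = cfg$points_per_octave,
                        criterion_db = cfg$criterion_db))
  logs <- c(logs, list(st$log)); stc <- st$value

  probe <- probe_config(f_p, cfg$L_p)
  st <- stage("ptc_tracking", {
    up <- simulate_listener_track(masker_config(f_p, "up"), probe, listener,
                                  seed = cfg$seed + 101)
    down <- simulate_listener_track(masker_config(f_p, "down"), probe,
                                    listener, seed = cfg$seed + 202)
    list(up = up, down = down)
  })
  logs <- c(logs, list(st$log)); tracks <- st$value

  st <- stage("ptc_analysis", analyze_ptc(tracks$up, tracks$down))
  logs <- c(logs, list(st$log)); ptc_res <- st$value

  st <- stage("metrics", {
    off_stc <- offset_ratios(stc)
    off_ptc <- offset_ratios(ptc_res$ptc)
    data.frame(
      cf = cfg$cf, f_p = f_p, L_p = cfg$L_p,
      q10_stc = q10(stc), q10_ptc = q10(ptc_res$ptc),
      stc_f_tip = stc$f_tip, stc_L_tip = stc$L_tip,
      ptc_f_tip = ptc_res$ptc$f_tip, ptc_L_tip = ptc_res$ptc$L_tip,
      stc_horizontal_pct = off_stc$horizontal_pct,
      stc_vertical_pct = off_stc$vertical_pct,
      ptc_horizontal_pct = off_ptc$horizontal_pct,
      ptc_vertical_pct = off_ptc$vertical_pct
    )
  })
  logs <- c(logs, list(st$log)); metrics <- st$value

  structure(
    list(fine_structure = fs, io_function = iof, stc = stc,
         ptc = ptc_res$ptc, ptc_sweeps = ptc_res, tracks = tracks,
         metrics = metrics,
         provenance = list(config = unclass(cfg), config_md5 = config_hash(cfg),
                           seed = cfg$seed,
                           package_version = as.character(
                             utils::packageVersion("oaetune")),
                           stages = logs)),
    class = "run_bundle"
  )
}

#' @export
print.run_bundle <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<run_bundle> CF %g Hz | f_p %.0f Hz, L_p %g dB SPL\n",
              m$cf, m$f_p, m$L_p))
  cat(sprintf("  STC: tip %.1f Hz @ %.1f dB, Q10 %.2f\n",
              m$stc_f_tip, m$stc_L_tip, m$q10_stc))
  cat(sprintf("  PTC: tip %.1f Hz @ %.1f dB, Q10 %.2f\n",
              m$ptc_f_tip, m$ptc_L_tip, m$q10_ptc))
  invisible(x)
}

#' Write a run bundle to a directory
#'
#' Writes the STC and PTC as curve CSVs, the two tracking records, the
#' metrics row, and a machine-readable provenance log (JSON) sufficient to
#' replay the run.
#'
#' @param bundle a `run_bundle` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curve_csv(bundle$stc, file.path(dir, "stc.csv"))
  write_curve_csv(bundle$ptc, file.path(dir, "ptc.csv"))
  write_track_csv(bundle$tracks$up, file.path(dir, "track_up.csv"))
  write_track_csv(bundle$tracks$down, file.path(dir, "track_down.csv"))
  utils::write.csv(bundle$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$provenance, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
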