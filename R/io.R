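# Readers/writers for the package's on-disk formats: tuning-curve CSV with a
# JSON header line, tracking-record CSV, Q10 tables, YAML/JSON configs, and
# the packaged Table-1 fixture.

json_header_line <- function(meta) {
  paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

read_json_header <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# "))
    stop_oaetune("missing JSON header line", "oaetune_bad_format")
  jsonlite::fromJSON(substring(first, 3))
}

#' Write a tuning curve to CSV
#'
#' The file is a two-column CSV (`frequency_hz`, `level_db`) preceded by a
#' commented JSON header carrying `kind`, `f_p`, `L_p` and `criterion_db`, so
#' the file is self-describing.
#'
#' @param curve a [tuning_curve()].
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tuning_curve"))
  meta <- list(kind = curve$kind, f_p = curve$f_p, L_p = curve$L_p,
               criterion_db = curve$criterion_db)
  writeLines(json_header_line(meta), path)
  suppressWarnings(utils::write.table(
    as.data.frame(curve), path, append = TRUE, sep = ",", row.names = FALSE,
    col.names = TRUE, qmethod = "double"
  ))
  invisible(path)
}

#' Read a tuning curve from CSV
#' @param path a file written by [write_curve_csv()].
#' @export
read_curve_csv <- function(path) {
  meta <- read_json_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  tuning_curve(df$frequency_hz, df$level_db, kind = meta$kind,
               f_p = meta$f_p, L_p = meta$L_p,
               criterion_db = if (is.null(meta$criterion_db)) NA_real_
                              else meta$criterion_db)
}

#' Write a tracking record to CSV
#'
#' One file holds the three row kinds of a Bekesy run, distinguished by which
#' columns are filled: event rows (`event` non-empty), per-segment frequency
#' rows (`segment` non-missing) and dense level-trajectory rows (the rest).
#' Columns: `time_s`, `event`, `masker_level_db`, `masker_fc_hz`, `segment`.
#'
#' @param track a [tracking_record()].
#' @param path output path.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "tracking_record"))
  meta <- list(sweep_dir = track$sweep_dir, f_p = track$f_p, L_p = track$L_p,
               lead_in_s = track$lead_in_s)
  ev <- track$events
  rows <- rbind(
    data.frame(time_s = ev$time_s, event = ev$event,
               masker_level_db = NA_real_, masker_fc_hz = NA_real_,
               segment = NA_integer_),
    data.frame(time_s = track$freq_traj$time_s, event = "",
               masker_level_db = NA_real_,
               masker_fc_hz = track$freq_traj$f_hz,
               segment = track$freq_traj$segment),
    data.frame(time_s = track$level_traj$time_s, event = "",
               masker_level_db = track$level_traj$level_db,
               masker_fc_hz = NA_real_, segment = NA_integer_)
  )
  writeLines(json_header_line(meta), path)
  suppressWarnings(utils::write.table(rows, path, append = TRUE, sep = ",",
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a tracking record from CSV
#' @param path a file written by [write_track_csv()].
#' @export
read_track_csv <- function(path) {
  meta <- read_json_header(path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(event = "character"))
  is_ev <- !is.na(df$event) & df$event != ""
  is_seg <- !is.na(df$segment)
  is_lev <- !is_ev & !is_seg
  tracking_record(
    events = data.frame(time_s = df$time_s[is_ev], event = df$event[is_ev],
                        stringsAsFactors = FALSE),
    level_traj = data.frame(time_s = df$time_s[is_lev],
                            level_db = df$masker_level_db[is_lev]),
    freq_traj = data.frame(time_s = df$time_s[is_seg],
                           segment = df$segment[is_seg],
                           f_hz = df$masker_fc_hz[is_seg]),
    sweep_dir = meta$sweep_dir, f_p = meta$f_p, L_p = meta$L_p,
    lead_in_s = meta$lead_in_s
  )
}

#' Read a Q10 record table
#'
#' Long-format CSV with columns `subject`, `cf`, `f_p_hz`, `q10_stc`,
#' `q10_ptc` (one row per subject and CF). All Q10 values must be positive.
#'
#' @param path CSV path; defaults to the packaged table of the 10
#'   normal-hearing subjects at CFs of 1, 2 and 4 kHz.
#' @export
read_q10_table <- function(path = system.file("extdata", "table1.csv",
                                              package = "oaetune")) {
  df <- utils::read.csv(path)
  need <- c("subject", "cf", "f_p_hz", "q10_stc", "q10_ptc")
  if (!all(need %in% names(df)))
    stop_oaetune(paste("Q10 table must have columns:",
                       paste(need, collapse = ", ")), "oaetune_bad_format")
  if (any(df$q10_stc <= 0 | df$q10_ptc <= 0))
    stop_oaetune("Q10 values must be positive", "oaetune_bad_format")
  df
}

#' Write a Q10 record table
#' @param records data.frame as in [read_q10_table()].
#' @param path output path.
#' @export
write_q10_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read or write any of the package's file formats
#'
#' Dispatcher over the supported formats. `kind` is one of `"wav"`
#' ([wav_read()]/[wav_write()]), `"trackcsv"`, `"curvecsv"`, `"q10csv"`,
#' `"config"` (YAML or JSON by extension). Writing requires `x`; reading
#' returns the typed object.
#'
#' @param path file path.
#' @param kind format name.
#' @param x object to write (omit to read).
#' @export
read_write_formats <- function(path, kind = c("wav", "trackcsv", "curvecsv",
                                              "q10csv", "config"),
                               x = NULL) {
  kind <- match.arg(kind)
  if (is.null(x)) {
    switch(kind,
      wav = wav_read(path),
      trackcsv = read_track_csv(path),
      curvecsv = read_curve_csv(path),
      q10csv = read_q10_table(path),
      config = read_config(path)
    )
  } else {
    switch(kind,
      wav = wav_write(x, path),
      trackcsv = write_track_csv(x, path),
      curvecsv = write_curve_csv(x, path),
      q10csv = write_q10_table(x, path),
      config = write_config(x, path)
    )
  }
}

#' Read a run configuration (YAML or JSON by extension)
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop_oaetune("config must be .yaml/.yml or .json",
                           "oaetune_bad_format")
  do.call(run_config, lst)
}

#' Write a run configuration (YAML or JSON by extension)
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else if (ext == "json")
    writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA), path)
  else stop_oaetune("config must be .yaml/.yml or .json", "oaetune_bad_format")
  invisible(path)
}
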