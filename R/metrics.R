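#' Q10 sharpness of a tuning curve
#'
#' Q10 is the tip frequency divided by the curve bandwidth 10 dB above the
#' tip. The two flank crossings of `L_tip + 10` dB are interpolated linearly
#' in (log2 frequency, dB); single missing points inside a flank are bridged
#' by the interpolation. If either flank never reaches 10 dB above the tip
#' the value is undefined and an error of class `oaetune_q10_undefined` is
#' raised (such curves are excluded from summaries).
#'
#' @param curve a [tuning_curve()].
#' @param rise_db bandwidth criterion above the tip (default 10 dB).
#' @return Q10 value (dimensionless).
#' @examples
#' # symmetric V, 20 dB/octave flanks: bandwidth 10 dB up is one octave
#' f <- 1000 * 2^seq(-1, 1, by = 0.1)
#' curve <- tuning_curve(f, 20 * abs(log2(f / 1000)) + 30, kind = "PTC")
#' q10(curve) # ~1 / (2^0.5 - 2^-0.5) = 1.414
#' @export
q10 <- function(curve, rise_db = 10) {
  stopifnot(inherits(curve, "tuning_curve"))
  ok <- is.finite(curve$levels)
  f <- curve$frequencies[ok]; l <- curve$levels[ok]
  if (!is.finite(curve$f_tip))
    stop_oaetune("curve has no tip", "oaetune_q10_undefined")
  target <- curve$L_tip + rise_db
  g <- log2(f)
  i_tip <- which.min(abs(g - log2(curve$f_tip)))
  cross <- function(idx_seq) {
    # walk outward from the tip to the first upward crossing of `target`
    for (m in seq_len(length(idx_seq) - 1)) {
      i <- idx_seq[m]; j <- idx_seq[m + 1]
      if (l[i] <= target && l[j] >= target) {
        if (l[j] == l[i]) return(2^g[j])
        return(2^(g[i] + (target - l[i]) / (l[j] - l[i]) * (g[j] - g[i])))
      }
    }
    NA_real_
  }
  f_hi <- if (i_tip < length(f)) cross(i_tip:length(f)) else NA_real_
  f_lo <- if (i_tip > 1) cross(i_tip:1) else NA_real_
  if (!is.finite(f_hi) || !is.finite(f_lo))
    stop_oaetune("a flank never reaches the +10 dB criterion; Q10 undefined",
                 "oaetune_q10_undefined")
  curve$f_tip / (f_hi - f_lo)
}

#' Tip offset ratios of a tuning curve
#'
#' Horizontal offset: `100 * (f_tip - f_p) / f_p`; vertical offset:
#' `100 * (L_tip - L_p) / L_p` (dB levels entered as plain numbers). Signs
#' are preserved; a positive horizontal offset means the tip lies above the
#' probe frequency.
#'
#' @param curve a [tuning_curve()] with a defined tip and nonzero `f_p`,
#'   `L_p`.
#' @return A list `horizontal_pct`, `vertical_pct`.
#' @export
offset_ratios <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  if (!is.finite(curve$f_tip))
    stop_oaetune("curve has no tip", "oaetune_no_tip")
  if (!is.finite(curve$f_p) || curve$f_p == 0 ||
      !is.finite(curve$L_p) || curve$L_p == 0)
    stop_oaetune("offset ratios need nonzero f_p and L_p", "oaetune_bad_curve")
  list(horizontal_pct = 100 * (curve$f_tip - curve$f_p) / curve$f_p,
       vertical_pct = 100 * (curve$L_tip - curve$L_p) / curve$L_p)
}

#' Per-CF summary of PTC/STC Q10 ratios with aberrant-point exclusion
#'
#' For each CF group, computes the ratio `q10_ptc / q10_stc` per subject,
#' drops aberrant ratios exceeding `aberrant_threshold` (default 1.5), and
#' returns the mean, sample SD (n-1 denominator) and retained count.
#'
#' @param records data.frame with columns `cf`, `q10_stc`, `q10_ptc` (e.g.
#'   from [read_q10_table()]).
#' @param aberrant_threshold ratios above this are excluded; `Inf` retains
#'   all.
#' @return A data.frame with one row per CF: `cf`, `mean_ratio`, `sd_ratio`,
#'   `n_retained`; the retained ratios are attached as attribute `"ratios"`
#'   (a list by CF).
#' @export
ratio_summary <- function(records, aberrant_threshold = 1.5) {
  stopifnot(all(c("cf", "q10_stc", "q10_ptc") %in% names(records)))
  cfs <- sort(unique(records$cf))
  kept <- lapply(cfs, function(cc) {
    r <- records$q10_ptc[records$cf == cc] / records$q10_stc[records$cf == cc]
    r[r <= aberrant_threshold]
  })
  names(kept) <- as.character(cfs)
  if (any(vapply(kept, length, integer(1)) < 2))
    stop_oaetune("fewer than 2 retained ratios in a CF group",
                 "oaetune_bad_summary")
  out <- data.frame(
    cf = cfs,
    mean_ratio = vapply(kept, mean, numeric(1)),
    sd_ratio = vapply(kept, stats::sd, numeric(1)),
    n_retained = vapply(kept, length, integer(1)),
    row.names = NULL
  )
  attr(out, "ratios") <- kept
  out
}

#' Paired t test (closed form)
#'
#' Standard two-sided paired t test on `x - y`, implemented from the
#' definition (mean and sample SD of the differences).
#'
#' @param x,y paired samples of equal length (>= 2).
#' @return A list `mean_diff`, `sd_diff`, `t`, `p`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_oaetune("x and y must be paired with length >= 2", "oaetune_bad_stats")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0)
    stop_oaetune("differences have zero variance; t undefined",
                 "oaetune_bad_stats")
  n <- length(d)
  tval <- mean(d) / (s / sqrt(n))
  list(mean_diff = mean(d), sd_diff = s, t = tval,
       p = 2 * stats::pt(-abs(tval), n - 1), df = n - 1)
}

#' One-way ANOVA (closed form)
#'
#' Standard fixed-effects one-way analysis of variance across groups,
#' implemented from the between/within sum-of-squares definitions.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return A list `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2))
    stop_oaetune("need >= 2 groups with >= 2 values each", "oaetune_bad_stats")
  all_x <- unlist(groups, use.names = FALSE)
  n <- length(all_x); k <- length(groups)
  grand <- mean(all_x)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1; df_w <- n - k
  if (ss_w == 0)
    stop_oaetune("zero within-group variance; F undefined", "oaetune_bad_stats")
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Comparative statistics over a Q10 record table
#'
#' Reproduces the comparison between objective (STC) and behavioral (PTC)
#' frequency selectivity on a Q10 table: per-CF means/SDs of both Q10
#' columns, the paired t test on STC - PTC across all pairs, the per-CF
#' Q10-ratio summaries with aberrant-point exclusion, and a one-way ANOVA of
#' the retained ratios across CFs.
#'
#' @param records data.frame with `cf`, `q10_stc`, `q10_ptc` (see
#'   [read_q10_table()]).
#' @param aberrant_threshold exclusion threshold for PTC/STC ratios.
#' @return A list: `per_cf` (means/SDs), `paired_t`, `ratio_summary`,
#'   `anova`.
#' @export
q10_statistics <- function(records, aberrant_threshold = 1.5) {
  cfs <- sort(unique(records$cf))
  per_cf <- do.call(rbind, lapply(cfs, function(cc) {
    g <- records[records$cf == cc, ]
    data.frame(cf = cc,
               mean_stc = mean(g$q10_stc), sd_stc = stats::sd(g$q10_stc),
               mean_ptc = mean(g$q10_ptc), sd_ptc = stats::sd(g$q10_ptc),
               n = nrow(g))
  }))
  rs <- ratio_summary(records, aberrant_threshold)
  list(per_cf = per_cf,
       paired_t = paired_t(records$q10_stc, records$q10_ptc),
       ratio_summary = rs,
       anova = oneway_anova(attr(rs, "ratios")))
}
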