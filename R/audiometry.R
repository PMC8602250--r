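#' Construct an audiogram
#'
#' Per-ear map from test frequency (Hz) to air-conduction threshold (dB HL).
#' Thresholds must lie in \[-10, 120\]; the six frequencies 250–8000 Hz are
#' required for shape classification, 125 Hz is optional.
#'
#' @param thresholds named numeric vector, names are frequencies in Hz.
#' @param subject subject id.
#' @param ear `"right"`, `"left"` or `"free_field"`.
#' @param visit visit index or label.
#' @return object of class `audiogram`.
#' @export
audiogram <- function(thresholds, subject = NA_character_, ear = "right",
                      visit = 1L) {
  freqs <- as.integer(names(thresholds))
  .check(!any(is.na(freqs)), "threshold names must be frequencies in Hz")
  .check(all(freqs %in% c(125L, 250L, 500L, 1000L, 2000L, 4000L, 8000L)),
         "unsupported audiometric frequency")
  .check(all(thresholds >= -10 & thresholds <= 120),
         "thresholds must lie in [-10, 120] dB HL")
  .check(ear %in% c("right", "left", "free_field"), "bad ear label: %s", ear)
  structure(list(thresholds = stats::setNames(as.numeric(thresholds), freqs),
                 subject = subject, ear = ear, visit = visit),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("<audiogram> %s (%s, visit %s)\n", x$subject, x$ear, x$visit))
  print(x$thresholds)
  invisible(x)
}

#' Pure tone average
#'
#' Arithmetic mean of the thresholds at the requested frequencies, unrounded.
#' The default four-frequency set (0.5/1/2/4 kHz) is the standard clinical
#' average.
#'
#' @param x an [audiogram()].
#' @param freqs frequencies (Hz) to average.
#' @return PTA in dB HL.
#' @export
pta <- function(x, freqs = c(500, 1000, 2000, 4000)) {
  stopifnot(inherits(x, "audiogram"))
  miss <- setdiff(as.character(freqs), names(x$thresholds))
  .check(length(miss) == 0L, "missing frequency: %s Hz",
         paste(miss, collapse = ", "))
  mean(x$thresholds[as.character(freqs)])
}

#' Grade the degree of hearing loss
#'
#' Bands (upper edges inclusive): normal <= 20, mild 21–40, moderate 41–55,
#' moderately severe 56–70, severe 71–90, profound > 90 dB HL.
#'
#' @param pta_db pure tone average in dB HL.
#' @return list with `category` and `pta`.
#' @export
grade_degree <- function(pta_db) {
  .check(is.numeric(pta_db) && pta_db >= -10 && pta_db <= 120,
         "PTA out of range [-10, 120]")
  category <- if (pta_db <= 20) "normal"
              else if (pta_db <= 40) "mild"
              else if (pta_db <= 55) "moderate"
              else if (pta_db <= 70) "moderately_severe"
              else if (pta_db <= 90) "severe"
              else "profound"
  list(category = category, pta = pta_db)
}

#' Classify audiogram shape
#'
#' Implements the mid-frequency (cookie-bite) inclusion rule: with the mid
#' band {1, 2, 4 kHz}, low band {250, 500 Hz} and high band {8 kHz}, let W be
#' the worst (largest) mid-band threshold. The curve is
#' `mid_frequency_typical` when W is the global worst threshold and exceeds
#' the *best* threshold of each flanking band by at least `margin_typical`
#' (20 dB); `mid_frequency_shallow` relaxes the margin to \[`margin_shallow`,
#' `margin_typical`) on at least one side while both sides stay at or above
#' `margin_shallow` (10 dB). `flat` means total range <= `flat_range` (15
#' dB); `high_frequency` / `low_frequency` are monotone curves with total
#' change >= `monotone_rise` (20 dB). Evaluation order is flat, typical,
#' shallow, high, low, other; exactly one label is returned.
#'
#' @param x an [audiogram()] with all six frequencies 250–8000 Hz.
#' @param margin_typical,margin_shallow,flat_range,monotone_rise dB knobs.
#' @return shape label.
#' @export
classify_shape <- function(x, margin_typical = 20, margin_shallow = 10,
                           flat_range = 15, monotone_rise = 20) {
  stopifnot(inherits(x, "audiogram"))
  need <- c("250", "500", "1000", "2000", "4000", "8000")
  miss <- setdiff(need, names(x$thresholds))
  .check(length(miss) == 0L, "missing frequency for shape classification: %s Hz",
         paste(miss, collapse = ", "))
  th <- x$thresholds[need]
  W <- max(th[c("1000", "2000", "4000")])
  low_margin <- W - min(th[c("250", "500")])
  high_margin <- W - th[["8000"]]
  if (max(th) - min(th) <= flat_range) return("flat")
  mid_worst <- W >= max(th)
  if (mid_worst && low_margin >= margin_typical && high_margin >= margin_typical)
    return("mid_frequency_typical")
  if (mid_worst && low_margin >= margin_shallow && high_margin >= margin_shallow &&
      (low_margin < margin_typical || high_margin < margin_typical))
    return("mid_frequency_shallow")
  d <- diff(th)
  if (all(d >= 0) && (th[["8000"]] - th[["250"]]) >= monotone_rise)
    return("high_frequency")
  if (all(d <= 0) && (th[["250"]] - th[["8000"]]) >= monotone_rise)
    return("low_frequency")
  "other"
}

#' Reproducibility of a mid-frequency phenotype across visits
#'
#' TRUE when at least two visits classify as a mid-frequency shape, or when a
#' single visit is already `mid_frequency_typical`. A shallow curve seen only
#' once is not accepted — borderline cases count only when the mid-frequency
#' configuration reproduces at follow-up.
#'
#' @param audiograms list of [audiogram()] visits for one subject/ear.
#' @return logical.
#' @export
confirm_reproducible <- function(audiograms) {
  .check(length(audiograms) >= 1L, "need at least one visit")
  shapes <- vapply(audiograms, classify_shape, character(1))
  mid <- startsWith(shapes, "mid_frequency")
  sum(mid) >= 2L || any(shapes == "mid_frequency_typical")
}

#' Read an audiogram table
#'
#' Long TSV with columns `subject`, `ear`, `visit`, `freq_hz`, `db_hl`;
#' returns one [audiogram()] per (subject, ear, visit).
#'
#' @param path path to the TSV.
#' @return named list of audiograms (`subject|ear|visit`).
#' @export
read_audiograms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("subject", "ear", "visit", "freq_hz", "db_hl") %in% names(df)),
         "audiogram table needs subject/ear/visit/freq_hz/db_hl")
  out <- lapply(split(df, paste(df$subject, df$ear, df$visit, sep = "|")),
                function(g) audiogram(stats::setNames(g$db_hl, g$freq_hz),
                                      subject = g$subject[1], ear = g$ear[1],
                                      visit = g$visit[1]))
  out
}
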