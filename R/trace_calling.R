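#' Methylation-density categories
#'
#' The four-category reference index used to score each CpG site of a
#' direct-sequencing chromatogram, plus `MISSING` for unreadable sites
#' (rendered `"x"` in tabular output).
#'
#' @format Character vector of category labels in increasing methylation
#'   order, `MISSING` last.
#' @export
SITE_CATEGORIES <- c("T_ONLY", "C_LE_T", "C_GT_T", "C_ONLY", "MISSING")

#' Calibration index for chromatogram classification
#'
#' Carries the detection noise floor and the methylated-fraction band edges
#' that the four categories were calibrated against using reconstituted
#' standards of methylated and unmethylated DNA. Classification itself uses
#' only peak comparisons (detected/undetected, C versus T); the fraction
#' bands are interpretation metadata attached by [category_to_band()].
#'
#' @param noise_floor_rel A channel is "not detected" when its height is at
#'   or below this fraction of the larger channel at the same position
#'   (default 0.05). The sequencer's detection limit is not a published
#'   constant; this default is a package choice.
#' @param noise_floor_abs Absolute height floor applied in addition
#'   (default 0, arbitrary fluorescence units).
#' @param band_low,band_high Methylated-fraction breakpoints of the
#'   category bands (defaults 0.10 and 0.25).
#' @return An object of class `calibration_index`.
#' @export
calibration_index <- function(noise_floor_rel = 0.05, noise_floor_abs = 0,
                              band_low = 0.10, band_high = 0.25) {
  stopifnot(noise_floor_rel >= 0, noise_floor_abs >= 0,
            0 < band_low, band_low < band_high, band_high < 1)
  structure(
    list(noise_floor_rel = noise_floor_rel, noise_floor_abs = noise_floor_abs,
         band_low = band_low, band_high = band_high),
    class = "calibration_index"
  )
}

peak_detected <- function(height, other, cal) {
  floor_ <- pmax(cal$noise_floor_rel * pmax(height, other), cal$noise_floor_abs)
  height > floor_
}

#' Classify one CpG site from its C and T peak heights
#'
#' Implements the reference index literally: `T_ONLY` when only T is
#' detected (no methylation), `C_ONLY` when only C is detected (methylation
#' on ~25% or more of molecules), `C_GT_T` when both are detected and C
#' exceeds T (~10-25%), `C_LE_T` when both are detected and C is at or
#' below T (<10%); ties go to `C_LE_T`. `MISSING` when neither channel
#' rises above the noise floor.
#'
#' @param height_C,height_T Nonnegative peak heights (vectorized).
#' @param cal A [calibration_index()].
#' @return Character vector of categories.
#' @export
classify_site <- function(height_C, height_T, cal = calibration_index()) {
  if (any(height_C < 0 | height_T < 0)) stop("peak heights must be nonnegative")
  det_c <- peak_detected(height_C, height_T, cal)
  det_t <- peak_detected(height_T, height_C, cal)
  out <- rep("MISSING", length(height_C))
  out[det_c & !det_t] <- "C_ONLY"
  out[!det_c & det_t] <- "T_ONLY"
  both <- det_c & det_t
  out[both & height_C > height_T] <- "C_GT_T"
  out[both & height_C <= height_T] <- "C_LE_T"
  out
}

#' Map a category to its calibrated methylated-fraction band
#'
#' @param category Category label (vectorized); `MISSING` is an error.
#' @param cal A [calibration_index()].
#' @return A data frame with columns `lower`, `upper`, `lower_open`,
#'   `upper_open` giving the band of methylated fraction each category was
#'   calibrated to: `T_ONLY` the point `{0}`, `C_LE_T` `(0, 0.10)`,
#'   `C_GT_T` `[0.10, 0.25)`, `C_ONLY` `[0.25, 1]`.
#' @export
category_to_band <- function(category, cal = calibration_index()) {
  if (any(category == "MISSING")) stop("MISSING has no methylated-fraction band")
  if (!all(category %in% SITE_CATEGORIES)) stop("unknown category")
  bands <- data.frame(
    category = c("T_ONLY", "C_LE_T", "C_GT_T", "C_ONLY"),
    lower = c(0, 0, cal$band_low, cal$band_high),
    upper = c(0, cal$band_low, cal$band_high, 1),
    lower_open = c(FALSE, TRUE, FALSE, FALSE),
    upper_open = c(FALSE, TRUE, TRUE, FALSE)
  )
  out <- bands[match(category, bands$category), ]
  rownames(out) <- NULL
  out
}

band_contains <- function(band, fraction) {
  lo_ok <- if (band$lower_open) fraction > band$lower else fraction >= band$lower
  hi_ok <- if (band$upper_open) fraction < band$upper else fraction <= band$upper
  lo_ok && hi_ok
}

#' Bisulfite conversion efficiency from non-CpG cytosines
#'
#' Fraction of non-CpG reference-C positions that read as fully converted
#' (C channel at/below the noise floor, T channel above it). Incomplete
#' conversion leaves residual C signal at non-CpG positions and would
#' mimic methylation, hence the QC gate.
#'
#' @param peaks A peak table (see [read_peak_table()]): data frame with at
#'   least `ref_base`, `is_cpg`, `height_C`, `height_T`.
#' @param cal A [calibration_index()].
#' @return Conversion rate in `[0,1]`.
#' @export
conversion_efficiency <- function(peaks, cal = calibration_index()) {
  rows <- peaks[peaks$ref_base == "C" & !peaks$is_cpg, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no non-CpG cytosine positions: conversion QC undefined")
  converted <- !peak_detected(rows$height_C, rows$height_T, cal) &
    peak_detected(rows$height_T, rows$height_C, cal)
  mean(converted)
}

#' Call all CpG sites of one direct-sequencing sample
#'
#' Evaluates the conversion-efficiency QC gate first (samples must convert
#' more than `qc_threshold` of their non-CpG cytosines), then classifies
#' each analyzed CpG site with the reference index. Sites without a peak
#' row, or listed in `unreadable_sites`, are `MISSING`.
#'
#' @param peaks Peak table for one sample and strand.
#' @param site_map The `cpg_site_map`.
#' @param cal A [calibration_index()].
#' @param analyzed_range Site indices to call (default all sites in the map).
#' @param unreadable_sites Site indices forced to `MISSING` (e.g. downstream
#'   of a poly-T run on the antisense read).
#' @param qc_threshold Minimum conversion rate, strict inequality
#'   (default 0.95).
#' @return A `call_vector`: list with `sample_id`, `strand`, `calls` (named
#'   character vector over `analyzed_range`), `conversion_rate`, `qc_pass`.
#' @export
call_sample <- function(peaks, site_map, cal = calibration_index(),
                        analyzed_range = site_map$index,
                        unreadable_sites = integer(0),
                        qc_threshold = 0.95) {
  rate <- conversion_efficiency(peaks, cal)
  qc_pass <- rate > qc_threshold
  cpg <- peaks[peaks$is_cpg, , drop = FALSE]
  calls <- vapply(analyzed_range, function(i) {
    if (i %in% unreadable_sites) return("MISSING")
    row <- cpg[cpg$site_index == i, , drop = FALSE]
    if (nrow(row) == 0L) return("MISSING")
    classify_site(row$height_C[1], row$height_T[1], cal)
  }, character(1))
  names(calls) <- analyzed_range
  structure(
    list(sample_id = peaks$sample_id[1], strand = peaks$strand[1],
         calls = calls, conversion_rate = rate, qc_pass = qc_pass),
    class = "call_vector"
  )
}

#' @export
print.call_vector <- function(x, ...) {
  cat(sprintf("call_vector %s [%s] qc_pass=%s conv=%.3f\n", x$sample_id,
              x$strand, x$qc_pass, x$conversion_rate))
  abbrev <- c(T_ONLY = ".", C_LE_T = "-", C_GT_T = "+", C_ONLY = "#",
              MISSING = "x")
  cat(" ", paste(abbrev[x$calls], collapse = ""), "\n")
  invisible(x)
}
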