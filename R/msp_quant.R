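#' Fit a qPCR standard curve from a serial dilution series
#'
#' Least-squares fit of Cq against log10(input copies) over a serial
#' dilution of bisulfite-converted fully methylated DNA. The amplification
#' efficiency (fold amplification per cycle) follows from the slope as
#' `10^(-1/slope)`; a perfectly doubling assay has slope
#' `-log2(10) = -3.3219` cycles per decade and efficiency 2.
#'
#' @param series Data frame with columns `copies` (positive) and `cq`.
#' @param lod_copies Limit of detection in copies per assay (default 6).
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `lod_copies`, `cq_range`, `copy_range`.
#' @export
fit_standard_curve <- function(series, lod_copies = 6) {
  stopifnot(lod_copies > 0)
  if (nrow(series) < 3L) stop("at least 3 dilution points required")
  if (any(series$copies <= 0)) stop("copies must be positive")
  lx <- log10(series$copies)
  if (length(unique(lx)) < 2L) stop("zero variance in copy values")
  fit <- stats::lm(cq ~ lx, data = data.frame(cq = series$cq, lx = lx))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("standard curve slope must be negative")
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         efficiency = 10^(-1 / slope),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         lod_copies = lod_copies,
         cq_range = range(series$cq),
         copy_range = range(series$copies)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: cq = %.4f %+.4f*log10(copies)  E=%.3f  R2=%.4f  LOD=%g\n",
    x$intercept, x$slope, x$efficiency, x$r_squared, x$lod_copies))
  invisible(x)
}

#' Convert Cq values to methylated-copy estimates
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#' A reaction is "detected" only when its estimate reaches the limit of
#' detection; not-detected reactions (`NA` Cq) and sub-LOD estimates carry
#' `copies_per_assay = 0` for marker logic. Copy estimates are rescaled to
#' the nominal input of 150 copies via `normalized = copies * target /
#' input_copies`.
#'
#' @param cq Numeric vector of Cq values; `NA` = not detected.
#' @param curve A [standard_curve()].
#' @param input_copies Actual bisulfite-converted input per reaction, as
#'   measured by the BS-actin assay (default 150).
#' @param target Nominal input the results are normalized to (default 150).
#' @param sample_id,assay Metadata carried through.
#' @return A `quant_result` data frame: `sample_id`, `assay`, `cq`,
#'   `copies_raw`, `copies_per_assay`, `detected`, `input_copies`,
#'   `normalized_value`.
#' @export
quantify <- function(cq, curve, input_copies = 150, target = 150,
                     sample_id = "sample", assay = "sense") {
  copies_raw <- ifelse(is.na(cq), 0, 10^((cq - curve$intercept) / curve$slope))
  outside <- !is.na(cq) & (cq < curve$cq_range[1] | cq > curve$cq_range[2])
  if (any(outside)) {
    warning(sum(outside), " Cq value(s) outside the calibrated range; extrapolating")
  }
  detected <- !is.na(cq) & copies_raw >= curve$lod_copies
  copies <- ifelse(detected, copies_raw, 0)
  data.frame(
    sample_id = sample_id, assay = assay, cq = cq,
    copies_raw = copies_raw, copies_per_assay = copies, detected = detected,
    input_copies = input_copies,
    normalized_value = copies * target / input_copies,
    stringsAsFactors = FALSE
  )
}

#' Input-normalization factor from the BS-actin assay
#'
#' Bisulfite-converted input DNA is quantified with a methylation-neutral
#' BS-actin PCR before the marker assays; marker copy numbers are rescaled
#' to the nominal per-reaction input.
#'
#' @param bs_actin_copies Measured input copies (positive).
#' @param target Nominal input (default 150 copies).
#' @return Scaling factor `target / bs_actin_copies`.
#' @export
normalize_input <- function(bs_actin_copies, target = 150) {
  if (any(bs_actin_copies <= 0)) stop("bs_actin_copies must be positive")
  target / bs_actin_copies
}

#' Convert a DNA mass to genome copies
#'
#' Uses the conversion factor of 6 pg genomic DNA per cell; each cell
#' carries `copies_per_cell` copies of any single locus (2 for a diploid
#' genome; configurable because "copies" may be counted per haploid
#' genome).
#'
#' @param mass_pg DNA mass in picograms (nonnegative).
#' @param pg_per_cell Picograms of DNA per cell (default 6).
#' @param copies_per_cell Locus copies per cell (default 2).
#' @return Copy number.
#' @export
mass_to_copies <- function(mass_pg, pg_per_cell = 6, copies_per_cell = 2L) {
  if (any(mass_pg < 0)) stop("mass must be nonnegative")
  mass_pg / pg_per_cell * copies_per_cell
}

#' Average duplicate MSP reactions
#'
#' Reactions are run in duplicate; the mean of the two normalized values is
#' used for quantitative analysis. A sample counts as "methylation
#' detected" when either replicate reaches the limit of detection (the
#' positivity cutoff is *any* detectable methylation per nominal input);
#' not-detected replicates contribute 0 to the mean. Both rules are
#' configurable via `detect_rule`.
#'
#' @param results A `quant_result` data frame with exactly two rows for the
#'   same sample and assay.
#' @param detect_rule `"either"` (default) or `"both"`.
#' @return One-row data frame: `sample_id`, `assay`, `normalized_value`
#'   (mean), `detected`.
#' @export
average_duplicates <- function(results, detect_rule = c("either", "both")) {
  detect_rule <- match.arg(detect_rule)
  if (nrow(results) != 2L) stop("expected exactly two replicates")
  if (length(unique(results$sample_id)) != 1L ||
      length(unique(results$assay)) != 1L) {
    stop("replicates must share sample_id and assay")
  }
  detected <- if (detect_rule == "either") any(results$detected)
              else all(results$detected)
  data.frame(
    sample_id = results$sample_id[1], assay = results$assay[1],
    normalized_value = mean(results$normalized_value),
    detected = detected, stringsAsFactors = FALSE
  )
}
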