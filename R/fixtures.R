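#' Packaged toy promoter region
#'
#' A synthetic stand-in for the real promoter/first-exon region: 30 CpG
#' sites in sense 5'-3' order, regularly spaced CG-free spacers carrying
#' non-CpG cytosines on both strands (for conversion QC), and a 16-bp
#' poly-A stretch between CpG sites 20 and 21 whose antisense bisulfite
#' conversion yields the poly-T run that truncates the antisense read after
#' site 20. Built deterministically in code; also shipped as
#' `inst/extdata/toy_promoter.fasta`.
#'
#' @return A [reference_region()].
#' @export
toy_region <- function() {
  spacer <- "TTACCATGGATCACT"   # CG-free; 4 non-CpG C, 2 G per copy
  units <- paste0(rep(paste0(spacer, "CG"), 30), collapse = "")
  # split after unit 20 and insert the poly-A run
  head_len <- 20L * (nchar(spacer) + 2L)
  seq <- paste0("GATTACA",
                substr(units, 1L, head_len),
                strrep("A", 16L),
                substr(units, head_len + 1L, nchar(units)),
                "TGATTACA")
  reference_region(seq, accession_id = "TOY_PROMOTER",
                   description = "synthetic toy promoter with 30 CpG sites")
}

rep_cats <- function(counts) {
  rep(names(counts), times = counts)
}

make_group_vectors <- function(group, n_samples, counts, n_sites = 20L) {
  pool <- rep_cats(counts)
  stopifnot(length(pool) == n_samples * n_sites)
  # deterministic interleave so every sample holds a mix of categories
  pool <- pool[order(seq_along(pool) %% n_samples, seq_along(pool))]
  lapply(seq_len(n_samples), function(k) {
    calls <- pool[((k - 1L) * n_sites + 1L):(k * n_sites)]
    names(calls) <- seq_len(n_sites)
    structure(
      list(sample_id = sprintf("%s_%02d", group, k), strand = "antisense",
           calls = calls, conversion_rate = 1, qc_pass = TRUE),
      class = "call_vector")
  })
}

#' Printed antisense density tallies as call vectors
#'
#' Reconstructs, as call vectors, the published per-group antisense
#' category tallies of the direct-sequencing survey: 32 HCC samples with
#' 295 of 640 readable site-calls "C only", 32 matched adjacent non-tumor
#' samples with 29 of 542 readable calls "C only" (98 unreadable), and 16
#' pooled normal/hepatitis/cirrhosis samples with 0 of 295 readable calls
#' "C only" (25 unreadable). Only the "C only" counts and readable totals
#' are published; the split of the remaining readable calls among the
#' other three categories is an arbitrary deterministic fill and carries
#' no information.
#'
#' @return Named list of three lists of `call_vector`s: `HCC`,
#'   `adjacent_non_HCC`, `control` (pooled normal/hepatitis/cirrhosis).
#' @export
printed_density_fixture <- function() {
  fill <- function(total, c_only, missing = 0L) {
    rest <- total - c_only - missing
    third <- rest %/% 3L
    c(T_ONLY = third + rest - 3L * third, C_LE_T = third, C_GT_T = third,
      C_ONLY = c_only, MISSING = missing)
  }
  list(
    HCC = make_group_vectors("HCC", 32L, fill(640L, 295L)),
    adjacent_non_HCC = make_group_vectors("ADJ", 32L, fill(640L, 29L, 98L)),
    control = make_group_vectors("CTRL", 16L, fill(320L, 0L, 25L))
  )
}

#' Printed combined-marker cohort
#'
#' The 53 AFP-evaluable HCC cases of the published quadrant analysis,
#' reconstructed from the printed counts: 14 marker+/AFP+, 21
#' marker+/AFP-, 9 marker-/AFP+, 9 marker-/AFP-. AFP values are synthetic
#' placeholders on the correct side of the 20 ng/mL cutoff.
#'
#' @return Data frame with columns `sample_id`, `marker_pos`, `afp_ng_ml`.
#' @export
combined_marker_fixture <- function() {
  quadrant <- function(n, marker, afp) {
    data.frame(marker_pos = rep(marker, n), afp_ng_ml = rep(afp, n))
  }
  df <- rbind(quadrant(14L, TRUE, 120), quadrant(21L, TRUE, 5),
              quadrant(9L, FALSE, 55), quadrant(9L, FALSE, 2))
  df$sample_id <- sprintf("HCC_%02d", seq_len(nrow(df)))
  df[c("sample_id", "marker_pos", "afp_ng_ml")]
}
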