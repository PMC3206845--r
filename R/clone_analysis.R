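#' Construct a clone call matrix
#'
#' Binary per-clone, per-site methylation calls from cloning-and-sequencing
#' of one bisulfite PCR product. Each clone derives from a single molecule,
#' so each site reads either "C only" (methylated, 1) or "T only"
#' (unmethylated, 0); `NA` marks unreadable entries.
#'
#' @param calls Matrix or data frame of 0/1/`NA`, clones in rows, sites in
#'   columns; column names are site indices.
#' @param sample_id,strand Sample metadata.
#' @return An object of class `clone_call_matrix`.
#' @export
clone_call_matrix <- function(calls, sample_id = "sample", strand = "antisense") {
  m <- as.matrix(calls)
  mode(m) <- "numeric"
  if (!all(m %in% c(0, 1) | is.na(m))) stop("clone calls must be 0, 1 or NA")
  if (nrow(m) < 1L) stop("at least one clone required")
  if (is.null(colnames(m))) colnames(m) <- seq_len(ncol(m))
  rownames(m) <- NULL
  structure(
    list(sample_id = sample_id, strand = strand, calls = m,
         clone_count = nrow(m)),
    class = "clone_call_matrix"
  )
}

#' Per-site percent methylation across clones
#'
#' For each site, methylated clones divided by clones with a readable call.
#' Sites where every clone is unreadable are dropped from the result rather
#' than reported as 0.
#'
#' @param mat A [clone_call_matrix()].
#' @return Named numeric vector of per-site fractions in `[0,1]`.
#' @export
percent_methylation <- function(mat) {
  frac <- colMeans(mat$calls, na.rm = TRUE)
  frac[!is.nan(frac)]
}

#' Pooled methylation-density contrast between two tissue groups
#'
#' Pools methylated and unmethylated site-calls over all clones and samples
#' of each group and compares the two groups with a two-sided Pearson
#' chi-squared test on the 2x2 table (no continuity correction), matching
#' how cloning-and-sequencing density is compared between tissue groups.
#'
#' @param group_a,group_b Lists of [clone_call_matrix()] objects.
#' @return List with `table` (2x2 counts), `chi2`, `df`, `p`.
#' @export
pooled_density_test <- function(group_a, group_b) {
  pool <- function(group) {
    if (length(group) == 0L) stop("both groups must be nonempty")
    calls <- unlist(lapply(group, function(m) as.vector(m$calls)))
    c(methylated = sum(calls == 1, na.rm = TRUE),
      unmethylated = sum(calls == 0, na.rm = TRUE))
  }
  tab <- rbind(a = pool(group_a), b = pool(group_b))
  res <- pearson_chi2(tab)
  list(table = tab, chi2 = res$chi2, df = res$df, p = res$p)
}
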