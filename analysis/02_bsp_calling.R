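#!/usr/bin/env Rscript
# Stage 2: conversion QC, chromatogram calling, density tallies.
#
# Applies the >95% non-CpG conversion gate, classifies every CpG site of
# every sample/strand with the four-category reference index, tallies
# categories per tissue group on the antisense strand, and contrasts HCC
# against benign liver with a Pearson chi-squared test. Also computes the
# >=50%-site BSP positivity rule and its strand-specificity.

suppressMessages(library(strandmeth))

cohort <- read_cohort("results/cohort")
config <- run_config()
vectors <- bsp_calling_stage(cohort$peaks, cohort$site_map, config)
qc <- vapply(vectors, `[[`, logical(1), "qc_pass")
message(sprintf("%d/%d sample-strand reads passed conversion QC",
                sum(qc), length(qc)))
vectors <- vectors[qc]
write_call_vectors(vectors, "results/call_vectors.tsv")

group_of <- setNames(cohort$samples$group, cohort$samples$sample_id)
strands <- vapply(vectors, `[[`, character(1), "strand")
vg <- unname(group_of[vapply(vectors, `[[`, character(1), "sample_id")])

anti <- strands == "antisense" &
  vg %in% c("HCC", "adjacent_non_HCC", "normal_liver", "hepatitis", "cirrhosis")
tal <- density_tally(vectors[anti], vg[anti])
write.table(cbind(group = rownames(tal$counts), as.data.frame(tal$counts)),
            "results/antisense_tally.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
fr <- tally_fraction(tal)
for (g in names(fr)) {
  message(sprintf("  %-18s C-only %d/%d (%.1f%%)", g, fr[[g]]$count,
                  fr[[g]]$total, 100 * fr[[g]]$fraction))
}
chi <- pearson_chi2(rbind(
  HCC = c(fr$HCC$count, fr$HCC$total - fr$HCC$count),
  normal = c(fr$normal_liver$count, fr$normal_liver$total - fr$normal_liver$count)))
message(sprintf("HCC vs normal antisense C-only: chi2=%.1f, p=%.3g",
                chi$chi2, chi$p))

pos <- vapply(vectors, bsp_positive, logical(1))
for (s in c("sense", "antisense")) {
  keep <- strands == s & !is.na(pos) & vg %in% c(
    "HCC", "adjacent_non_HCC", "normal_liver", "hepatitis", "cirrhosis")
  ss <- sensitivity_specificity(pos[keep], vg[keep] == "HCC")
  message(sprintf("BSP %-9s positivity: sensitivity %.0f%%, specificity %.0f%%",
                  s, 100 * ss$sensitivity, 100 * ss$specificity))
}
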