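#!/usr/bin/env Rscript
# Stage 3: cloning-and-sequencing analysis of the antisense strand.
#
# Per-clone binary calls give per-site percent methylation for each
# sampled tissue; methylated/unmethylated site-calls pooled over clones
# and samples are contrasted between tissue groups.

suppressMessages(library(strandmeth))

cohort <- read_cohort("results/cohort")
group_of <- setNames(cohort$samples$group, cohort$samples$sample_id)

pm <- lapply(cohort$clones, percent_methylation)
tab <- do.call(rbind, lapply(names(pm), function(id) {
  data.frame(sample_id = id, group = unname(group_of[[id]]),
             site = as.integer(names(pm[[id]])),
             percent_methylation = round(100 * unname(pm[[id]]), 1))
}))
write.table(tab, "results/clone_percent_methylation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("percent methylation for %d cloned samples written", length(pm)))

groups <- vapply(cohort$clones, function(m) unname(group_of[[m$sample_id]]),
                 character(1))
by_group <- split(cohort$clones, groups)
for (cmp in list(c("HCC", "normal_liver"), c("HCC", "adjacent_non_HCC"))) {
  res <- pooled_density_test(by_group[[cmp[1]]], by_group[[cmp[2]]])
  message(sprintf("%s vs %s pooled clone density: chi2=%.1f, p=%.3g",
                  cmp[1], cmp[2], res$chi2, res$p))
}
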