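#!/usr/bin/env Rscript
# Regenerates the packaged fixtures under inst/extdata/ (deterministic).
# The shipped mini cohort carries chromatogram peak tables for a subset of
# samples only, mirroring a study design where direct sequencing covers a
# subset of the MSP cohort, and keeping the fixture small.

suppressMessages(library(strandmeth))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_region_fasta(toy_region(), "inst/extdata/toy_promoter.fasta")

cfg <- default_generator_config(seed = 271828L)
cfg$cohort_sizes <- c(HCC = 4L, adjacent_non_HCC = 4L, cirrhosis = 3L,
                      hepatitis = 3L, normal_liver = 2L, nonliver = 1L,
                      fetal_liver = 0L, mouse_liver = 1L)
cfg$clone$samples_per_group <- c(HCC = 2L, adjacent_non_HCC = 2L,
                                 normal_liver = 2L)
cohort <- generate_cohort(cfg)
bsp_subset <- c("HCC_01", "HCC_02", "ADJ_01", "CIR_01", "HEP_01", "NL_01")
cohort$peaks <- cohort$peaks[cohort$peaks$sample_id %in% bsp_subset, ]
write_cohort(cohort, "inst/extdata/mini_cohort")
message("fixtures written under inst/extdata/")
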