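#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic cohort.
#
# The generator emulates the study conditions: 58 HCC with 58 matched
# adjacent non-tumor livers, 41 cirrhosis, 39 hepatitis, 6 normal livers,
# plus nonhepatic/fetal/murine negative controls; antisense-strand
# background methylation in all adult liver groups and dense two-strand
# methylation mostly in HCC. Every downstream stage reads the files this
# stage writes.

suppressMessages(library(strandmeth))

seed <- 20260924L
cfg <- default_generator_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

message(sprintf("cohort of %d samples written to results/cohort (seed %d)",
                nrow(cohort$samples), seed))
print(table(cohort$samples$group))
message(sprintf("truth: %d/%d HCC sense-positive, %d/%d antisense-positive",
                sum(cohort$truth$truth_pos_sense[cohort$truth$group == "HCC"]),
                sum(cohort$truth$group == "HCC"),
                sum(cohort$truth$truth_pos_antisense[cohort$truth$group == "HCC"]),
                sum(cohort$truth$group == "HCC")))
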