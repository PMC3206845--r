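#!/usr/bin/env Rscript
# Stage 4: quantitative MSP.
#
# Fits a standard curve per assay from the ten-fold dilution series,
# measures each sample's input with the BS-actin assay, converts marker
# Cq values to methylated copies per 150 input copies with the 6-copy
# limit of detection, and averages duplicates.

suppressMessages(library(strandmeth))

cohort <- read_cohort("results/cohort")
mq <- suppressWarnings(msp_quant_stage(cohort$msp, cohort$dilutions))

for (a in names(mq$curves)) {
  cu <- mq$curves[[a]]
  message(sprintf(
    "  %-10s slope %.3f cycles/log10, efficiency %.3f, R2 %.4f, LOD %g copies",
    a, cu$slope, cu$efficiency, cu$r_squared, cu$lod_copies))
  write_standard_curve(cu, sprintf("results/curve_%s.json", a))
}

quant <- mq$quant
quant$normalized_value <- round(quant$normalized_value, 4)
quant$input_copies <- round(quant$input_copies, 2)
write.table(quant, "results/msp_quant.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
det <- with(quant, tapply(detected, assay, mean))
message(sprintf("detected methylation in %.0f%% (sense) / %.0f%% (antisense) of samples",
                100 * det[["sense"]], 100 * det[["antisense"]]))
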