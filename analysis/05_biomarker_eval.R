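#!/usr/bin/env Rscript
# Stage 5: biomarker evaluation.
#
# Runs the full evaluation on the simulated cohort: MSP
# sensitivity/specificity per strand at the any-detectable-methylation
# cutoff, ROC curves with the paired DeLong comparison, the combined
# marker-plus-AFP quadrant analysis on HCC, and the clinicopathological
# group tests; writes the complete report to results/report.json.

suppressMessages(library(strandmeth))

report <- suppressWarnings(run_pipeline("results/cohort", "results"))

m <- report$msp
message(sprintf("MSP sense:     sensitivity %.1f%%, specificity %.1f%%, AUROC %.3f",
                100 * m$sense$sensitivity, 100 * m$sense$specificity,
                m$auroc_sense))
message(sprintf("MSP antisense: sensitivity %.1f%%, specificity %.1f%%, AUROC %.3f",
                100 * m$antisense$sensitivity, 100 * m$antisense$specificity,
                m$auroc_antisense))
message(sprintf("paired ROC comparison p = %.4f", m$roc_comparison_p))

cmb <- report$combined_marker
message(sprintf(
  "combined marker (n=%d HCC with AFP): marker+ %.0f%%, union %.0f%%, marker+/AFP- %.0f%% of marker+",
  cmb$n, cmb$pct_marker_pos, cmb$pct_union_pos,
  cmb$pct_marker_pos_afp_neg_of_marker_pos))

gt <- report$group_tests
message(sprintf("stage (1 vs 2-4) Kruskal-Wallis p = %.3f; Spearman marker~AFP p = %.3f",
                gt$kruskal_wallis$stage$p, gt$spearman_marker_afp$p))
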