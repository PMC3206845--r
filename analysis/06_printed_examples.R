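#!/usr/bin/env Rscript
# Stage 6: worked examples from the published counts.
#
# Reconstructs the published per-group antisense category tallies and the
# 53-case combined-marker quadrants as fixtures, recomputes the headline
# percentages with the package's own tally and quadrant machinery, and
# contrasts HCC against benign liver with the Pearson chi-squared test.

suppressMessages(library(strandmeth))

fx <- printed_density_fixture()
vectors <- c(fx$HCC, fx$adjacent_non_HCC, fx$control)
groups <- rep(c("HCC", "adjacent_non_HCC", "control"), c(32, 32, 16))
fr <- tally_fraction(density_tally(vectors, groups))
message(sprintf("HCC antisense C-only:      %d/%d = %.1f%%",
                fr$HCC$count, fr$HCC$total, 100 * fr$HCC$fraction))
message(sprintf("adjacent antisense C-only: %d/%d = %.1f%%",
                fr$adjacent_non_HCC$count, fr$adjacent_non_HCC$total,
                100 * fr$adjacent_non_HCC$fraction))
message(sprintf("benign liver C-only:       %d/%d",
                fr$control$count, fr$control$total))

chi <- pearson_chi2(rbind(c(fr$HCC$count, fr$HCC$total - fr$HCC$count),
                          c(fr$control$count,
                            fr$control$total - fr$control$count)))
message(sprintf("density contrast: chi2 = %.1f, p = %.3g", chi$chi2, chi$p))

cm <- combined_marker_fixture()
res <- combined_marker(cm$marker_pos, cm$afp_ng_ml, afp_cutoff = 20)
message(sprintf("methylation marker positive: %.0f%% (%d/%d)",
                res$pct_marker_pos, sum(cm$marker_pos), res$n))
message(sprintf("AFP positive:                %.0f%%", res$pct_afp_pos))
message(sprintf("positive for either:         %.0f%%", res$pct_union_pos))
message(sprintf("AFP-negative among marker+:  %.0f%%",
                res$pct_marker_pos_afp_neg_of_marker_pos))
message(sprintf("added over AFP alone:        %.0f%%",
                res$pct_additional_over_afp))
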