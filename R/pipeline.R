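#' Pipeline run configuration
#'
#' Collects the analysis constants: conversion-QC threshold (strict >0.95),
#' BSP positivity threshold (>=50% of readable sites), MSP limit of
#' detection (6 copies/assay), nominal input (150 copies/reaction), AFP
#' positivity cutoff (>=20 ng/mL), and the analyzed site ranges per strand.
#'
#' @param qc_threshold Conversion-rate gate, strict inequality.
#' @param bsp_threshold BSP positivity fraction, inclusive.
#' @param lod_copies MSP limit of detection (copies per assay).
#' @param input_target Nominal input copies per MSP reaction.
#' @param afp_cutoff AFP positivity cutoff (ng/mL, inclusive).
#' @param analyzed_range_sense,analyzed_range_antisense Site indices called
#'   per strand (the antisense read is truncated after site 20 by the
#'   poly-T run).
#' @param cal A [calibration_index()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(qc_threshold = 0.95, bsp_threshold = 0.5,
                       lod_copies = 6, input_target = 150, afp_cutoff = 20,
                       analyzed_range_sense = 1:20,
                       analyzed_range_antisense = 1:20,
                       cal = calibration_index()) {
  stopifnot(qc_threshold > 0, qc_threshold < 1,
            bsp_threshold > 0, bsp_threshold <= 1,
            lod_copies > 0, input_target > 0, afp_cutoff >= 0)
  structure(
    list(qc_threshold = qc_threshold, bsp_threshold = bsp_threshold,
         lod_copies = lod_copies, input_target = input_target,
         afp_cutoff = afp_cutoff,
         analyzed_range_sense = analyzed_range_sense,
         analyzed_range_antisense = analyzed_range_antisense,
         cal = cal),
    class = "run_config")
}

control_groups <- function() {
  c("adjacent_non_HCC", "normal_liver", "hepatitis", "cirrhosis")
}

#' MSP quantification stage for a measurement table
#'
#' Fits one standard curve per assay from the dilution series, measures
#' each sample's actual input with the BS-actin assay (mean of duplicate
#' raw copy estimates), quantifies the marker assays against their curves
#' normalized to the nominal input, and averages duplicates with the
#' either-replicate detection rule.
#'
#' @param msp Measurement data frame (`sample_id, assay, replicate, cq`).
#' @param dilutions Dilution-series data frame (`assay_id, copies, cq`).
#' @param config A [run_config()].
#' @return List with `curves` (per assay) and `quant`, a data frame with
#'   one row per sample and marker assay (`normalized_value`, `detected`,
#'   `input_copies`).
#' @export
msp_quant_stage <- function(msp, dilutions, config = run_config()) {
  assays <- unique(dilutions$assay_id)
  curves <- lapply(stats::setNames(assays, assays), function(a) {
    fit_standard_curve(dilutions[dilutions$assay_id == a, , drop = FALSE],
                       lod_copies = config$lod_copies)
  })
  actin <- msp[msp$assay == "bs_actin", , drop = FALSE]
  input_by_sample <- vapply(split(actin, actin$sample_id), function(d) {
    q <- quantify(d$cq, curves$bs_actin, sample_id = d$sample_id[1],
                  assay = "bs_actin")
    mean(q$copies_raw)
  }, numeric(1))
  marker <- msp[msp$assay != "bs_actin", , drop = FALSE]
  quant <- do.call(rbind, lapply(
    split(marker, list(marker$sample_id, marker$assay), drop = TRUE),
    function(d) {
      input <- input_by_sample[[d$sample_id[1]]]
      if (is.null(input) || !is.finite(input) || input <= 0) {
        warning("no usable BS-actin input for ", d$sample_id[1],
                "; assuming nominal input")
        input <- config$input_target
      }
      q <- quantify(d$cq, curves[[d$assay[1]]], input_copies = input,
                    target = config$input_target,
                    sample_id = d$sample_id[1], assay = d$assay[1])
      out <- average_duplicates(q)
      out$input_copies <- input
      out
    }))
  rownames(quant) <- NULL
  list(curves = curves, quant = quant)
}

#' BSP calling stage for a peak table
#'
#' Calls every sample/strand of a long peak table with the reference
#' index, applying the conversion-QC gate; QC failures are retained with
#' `qc_pass = FALSE` and excluded from downstream tallies.
#'
#' @param peaks Long peak table covering multiple samples and strands.
#' @param site_map The `cpg_site_map`.
#' @param config A [run_config()].
#' @return Named list of `call_vector`s (names `sample_id.strand`).
#' @export
bsp_calling_stage <- function(peaks, site_map, config = run_config()) {
  parts <- split(peaks, list(peaks$sample_id, peaks$strand), drop = TRUE)
  lapply(parts, function(d) {
    rng <- if (d$strand[1] == "antisense") config$analyzed_range_antisense
           else config$analyzed_range_sense
    call_sample(d, site_map, cal = config$cal, analyzed_range = rng,
                qc_threshold = config$qc_threshold)
  })
}

#' Evaluate a cohort end to end
#'
#' Runs every applicable stage on an in-memory cohort (as produced by
#' [generate_cohort()] or [read_cohort()]): conversion QC and chromatogram
#' calling, per-group density tallies with chi-squared contrasts, BSP
#' positivity and its sensitivity/specificity, clone percent-methylation
#' and pooled density tests, MSP standard curves and quantification,
#' MSP sensitivity/specificity at the LOD cutoff, ROC curves with paired
#' DeLong comparison, the combined marker-plus-AFP analysis on HCC, and
#' clinicopathological group tests. Stages whose inputs are absent are
#' skipped and reported as `NULL`.
#'
#' @param cohort Cohort list (`samples`, `msp`, `dilutions`, optionally
#'   `peaks`, `clones`, `site_map`).
#' @param config A [run_config()].
#' @return A nested report list.
#' @export
evaluate_cohort <- function(cohort, config = run_config()) {
  samples <- cohort$samples
  if (is.null(samples) || nrow(samples) == 0L) stop("empty cohort")
  report <- list(n_samples = nrow(samples),
                 groups = as.list(table(samples$group)))
  group_of <- stats::setNames(samples$group, samples$sample_id)

  ## BSP sequencing arm
  if (!is.null(cohort$peaks)) {
    vectors <- bsp_calling_stage(cohort$peaks, cohort$site_map, config)
    qc <- vapply(vectors, `[[`, logical(1), "qc_pass")
    if (!any(qc)) stop("no samples passed QC")
    if (any(!qc)) {
      message(sum(!qc), " sample-strand reads failed conversion QC and were dropped")
    }
    vectors <- vectors[qc]
    strand_of <- vapply(vectors, `[[`, character(1), "strand")
    vgroups <- unname(group_of[vapply(vectors, `[[`, character(1), "sample_id")])

    tally_pair <- function(strand, a, b, mode) {
      keep <- strand_of == strand & vgroups %in% c(a, b)
      if (sum(vgroups[keep] == a) == 0L || sum(vgroups[keep] == b) == 0L) {
        return(NULL)
      }
      t <- density_tally(vectors[keep], vgroups[keep], mode = mode)
      counts <- t$counts[c(a, b), setdiff(colnames(t$counts), "MISSING"),
                         drop = FALSE]
      chi <- tryCatch(pearson_chi2(counts[, colSums(counts) > 0, drop = FALSE]),
                      error = function(e) NULL)
      list(counts = counts, sites_used = t$sites_used, chi2 = chi,
           c_only = tally_fraction(t))
    }
    report$bsp <- list(
      n_called = length(vectors), n_qc_failed = sum(!qc),
      hcc_vs_normal_antisense = lapply(
        stats::setNames(c("all_available", "complete_cases"),
                        c("all_available", "complete_cases")),
        function(m) tally_pair("antisense", "HCC", "normal_liver", m)),
      hcc_vs_adjacent_antisense = lapply(
        stats::setNames(c("all_available", "complete_cases"),
                        c("all_available", "complete_cases")),
        function(m) tally_pair("antisense", "HCC", "adjacent_non_HCC", m))
    )
    # strand positivity at the >=50% rule
    pos <- vapply(vectors, bsp_positive, logical(1),
                  threshold_frac = config$bsp_threshold)
    sens_spec_strand <- function(strand) {
      keep <- strand_of == strand &
        vgroups %in% c("HCC", control_groups()) & !is.na(pos)
      if (!any(vgroups[keep] == "HCC") || all(vgroups[keep] == "HCC")) {
        return(NULL)
      }
      sensitivity_specificity(pos[keep], vgroups[keep] == "HCC")
    }
    report$bsp$positivity <- list(sense = sens_spec_strand("sense"),
                                  antisense = sens_spec_strand("antisense"))
  }

  ## clone arm
  if (!is.null(cohort$clones) && length(cohort$clones) > 0L) {
    cgroups <- vapply(cohort$clones, function(m) unname(group_of[m$sample_id]),
                      character(1))
    by_group <- split(cohort$clones, cgroups)
    ptest <- function(a, b) {
      if (is.null(by_group[[a]]) || is.null(by_group[[b]])) return(NULL)
      res <- pooled_density_test(by_group[[a]], by_group[[b]])
      res$table <- NULL
      res
    }
    report$clones <- list(
      percent_methylation = lapply(cohort$clones, percent_methylation),
      hcc_vs_normal = ptest("HCC", "normal_liver"),
      hcc_vs_adjacent = ptest("HCC", "adjacent_non_HCC")
    )
  }

  ## MSP arm
  if (!is.null(cohort$msp)) {
    mq <- msp_quant_stage(cohort$msp, cohort$dilutions, config)
    quant <- mq$quant
    report$msp <- list(curves = lapply(mq$curves, function(cu) {
      unclass(cu)[c("slope", "intercept", "efficiency", "r_squared",
                    "lod_copies")]
    }))
    eval_strand <- function(assay) {
      q <- quant[quant$assay == assay, , drop = FALSE]
      g <- unname(group_of[q$sample_id])
      keep <- g %in% c("HCC", control_groups())
      q <- q[keep, , drop = FALSE]; g <- g[keep]
      list(quant = q, groups = g, is_case = g == "HCC")
    }
    se <- eval_strand("sense"); an <- eval_strand("antisense")
    if (any(se$is_case) && !all(se$is_case)) {
      roc_s <- roc_curve(se$quant$normalized_value, se$is_case)
      roc_a <- roc_curve(an$quant$normalized_value, an$is_case)
      report$msp$sense <- sensitivity_specificity(se$quant$detected, se$is_case)
      report$msp$antisense <- sensitivity_specificity(an$quant$detected,
                                                      an$is_case)
      report$msp$auroc_sense <- roc_s$auroc
      report$msp$auroc_antisense <- roc_a$auroc
      report$msp$roc_comparison_p <- compare_roc(roc_s, roc_a)
    }
    # combined marker on HCC with AFP, sense assay
    hcc_sense <- quant[quant$assay == "sense" &
                         group_of[quant$sample_id] == "HCC", , drop = FALSE]
    afp <- samples$afp_ng_ml[match(hcc_sense$sample_id, samples$sample_id)]
    if (any(!is.na(afp))) {
      report$combined_marker <- combined_marker(hcc_sense$detected, afp,
                                                afp_cutoff = config$afp_cutoff)
      report$combined_marker$quadrants <-
        as.list(stats::setNames(as.vector(report$combined_marker$quadrants),
                                c("marker_pos_afp_pos", "marker_neg_afp_pos",
                                  "marker_pos_afp_neg", "marker_neg_afp_neg")))
    }
    # clinicopathological tests on the quantitative sense marker
    cohort_df <- samples
    cohort_df$marker_value <- quant$normalized_value[
      match(paste(samples$sample_id, "sense"),
            paste(quant$sample_id, quant$assay))]
    liver <- cohort_df[cohort_df$group %in% c("HCC", control_groups()), ,
                       drop = FALSE]
    if (any(liver$group == "HCC")) {
      report$group_tests <- group_tests(liver, afp_cutoff = config$afp_cutoff)
    }
    report$quant <- quant
  }
  report
}

#' Run the full pipeline on a cohort directory
#'
#' Reads the interchange files written by [write_cohort()], evaluates the
#' cohort, and writes `report.json` plus human-readable TSV summaries
#' (`quant.tsv`, `call_vectors.tsv` when applicable) under `output_dir`.
#' Deterministic: no randomness is consumed, so repeated runs on the same
#' inputs produce byte-identical outputs.
#'
#' @param input_dir Cohort directory.
#' @param output_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, config = run_config()) {
  cohort <- read_cohort(input_dir)
  report <- evaluate_cohort(cohort, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  quant <- report$quant
  report$quant <- NULL
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       na = "null", pretty = TRUE)
  if (!is.null(quant)) {
    quant$normalized_value <- round(quant$normalized_value, 6)
    quant$input_copies <- round(quant$input_copies, 6)
    write_tsv_(quant, file.path(output_dir, "quant.tsv"))
  }
  if (!is.null(cohort$peaks)) {
    vectors <- bsp_calling_stage(cohort$peaks, cohort$site_map, config)
    write_call_vectors(vectors, file.path(output_dir, "call_vectors.tsv"))
  }
  invisible(report)
}
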