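#' Tally methylation-density categories per group
#'
#' Counts CpG site-calls in each of the four reference-index categories,
#' per tissue group, over a set of QC-passed call vectors. Two
#' site-inclusion modes are supported: `all_available` keeps every readable
#' call and simply drops `MISSING` entries; `complete_cases` first removes
#' any site that is missing in at least one sample of the comparison, then
#' tallies the remainder.
#'
#' @param vectors List of `call_vector` objects (see [call_sample()]).
#' @param groups Character vector of group labels, one per vector.
#' @param site_subset Site indices to restrict to (default: all sites
#'   present in the first vector).
#' @param mode `"all_available"` or `"complete_cases"`.
#' @return List with `counts` (groups x categories integer matrix including
#'   a `MISSING` column under `all_available`), `sites_used`, and `mode`.
#' @export
density_tally <- function(vectors, groups,
                          site_subset = NULL,
                          mode = c("all_available", "complete_cases")) {
  mode <- match.arg(mode)
  stopifnot(length(vectors) == length(groups))
  if (length(vectors) == 0L) stop("no call vectors supplied")
  if (is.null(site_subset)) site_subset <- as.integer(names(vectors[[1]]$calls))
  sites <- as.character(site_subset)
  call_mat <- t(vapply(vectors, function(v) {
    out <- rep("MISSING", length(sites))
    names(out) <- sites
    have <- intersect(sites, names(v$calls))
    out[have] <- v$calls[have]
    out
  }, character(length(sites))))
  colnames(call_mat) <- sites
  if (mode == "complete_cases") {
    keep <- colSums(call_mat == "MISSING") == 0L
    call_mat <- call_mat[, keep, drop = FALSE]
  }
  glev <- unique(groups)
  counts <- t(vapply(glev, function(g) {
    calls <- as.vector(call_mat[groups == g, , drop = FALSE])
    if (length(calls) == 0L) warning("empty group: ", g)
    vapply(SITE_CATEGORIES, function(cat) sum(calls == cat), integer(1))
  }, integer(length(SITE_CATEGORIES))))
  rownames(counts) <- glev
  list(counts = counts, sites_used = as.integer(colnames(call_mat)), mode = mode)
}

#' Fraction of readable sites in a given category
#'
#' Convenience accessor on a [density_tally()] result: per group, the count
#' in `category` divided by readable (non-MISSING) site-calls.
#'
#' @param tally A [density_tally()] result.
#' @param category Category label (default `"C_ONLY"`).
#' @return Named list per group with `count`, `total`, `fraction`.
#' @export
tally_fraction <- function(tally, category = "C_ONLY") {
  counts <- tally$counts
  readable <- rowSums(counts[, setdiff(colnames(counts), "MISSING"), drop = FALSE])
  lapply(stats::setNames(rownames(counts), rownames(counts)), function(g) {
    list(count = unname(counts[g, category]), total = unname(readable[g]),
         fraction = unname(counts[g, category] / readable[g]))
  })
}

#' Two-sided Pearson chi-squared test on a contingency table
#'
#' Standard Pearson statistic with `df = (r-1)(c-1)` and no continuity
#' correction (Yates correction disabled to match a plain Pearson test).
#'
#' @param table Matrix of nonnegative counts, at least 2x2.
#' @return List with `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be nonnegative")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2x2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' BSP positivity call for one sample
#'
#' A strand is "positive" when methylation is detected in at least
#' `threshold_frac` of its readable CpG sites. "Detected" defaults to any
#' category with visible C signal (everything except `T_ONLY`); the set is
#' configurable.
#'
#' @param v A `call_vector`.
#' @param threshold_frac Positivity threshold on the detected fraction,
#'   inclusive (default 0.5).
#' @param detected_categories Categories counted as methylation detected.
#' @return Logical flag; `NA` with a warning when every site is `MISSING`.
#' @export
bsp_positive <- function(v, threshold_frac = 0.5,
                         detected_categories = c("C_LE_T", "C_GT_T", "C_ONLY")) {
  calls <- v$calls[v$calls != "MISSING"]
  if (length(calls) == 0L) {
    warning("all sites MISSING for ", v$sample_id, "; positivity undefined")
    return(NA)
  }
  mean(calls %in% detected_categories) >= threshold_frac
}

#' MSP positivity call
#'
#' Positive iff methylation was detected (at or above the limit of
#' detection) per nominal input.
#'
#' @param q One-row `quant_result` (e.g. from [average_duplicates()]).
#' @return Logical flag.
#' @export
msp_positive <- function(q) isTRUE(as.logical(q$detected[1]))

#' Sensitivity and specificity of a binary marker
#'
#' Sensitivity over the case class, specificity over all control samples
#' (for the liver cohorts: adjacent non-tumor, normal, hepatitis and
#' cirrhosis pooled).
#'
#' @param calls Logical marker calls.
#' @param is_case Logical; `TRUE` for cases.
#' @return List with `sensitivity`, `specificity`, `n_case`, `n_control`.
#' @export
sensitivity_specificity <- function(calls, is_case) {
  stopifnot(length(calls) == length(is_case))
  keep <- !is.na(calls) & !is.na(is_case)
  calls <- calls[keep]; is_case <- is_case[keep]
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  list(sensitivity = mean(calls[is_case]),
       specificity = mean(!calls[!is_case]),
       n_case = sum(is_case), n_control = sum(!is_case))
}

#' Empirical ROC curve and AUROC
#'
#' Builds the empirical ROC of a quantitative marker (higher values
#' indicating case status) over all distinct thresholds, with ties taking
#' simultaneous steps; the area under the curve equals the Mann-Whitney
#' probability that a random case outscores a random control.
#'
#' @param values Numeric marker values.
#' @param is_case Logical; `TRUE` for cases.
#' @return A `roc_result`: list with `points` (data frame `threshold`,
#'   `sensitivity`, `fpr`), `auroc`, `n_pos`, `n_neg`, `values`, `is_case`
#'   (kept for paired curve comparison).
#' @export
roc_curve <- function(values, is_case) {
  stopifnot(length(values) == length(is_case))
  keep <- !is.na(values) & !is.na(is_case)
  values <- values[keep]; is_case <- as.logical(is_case[keep])
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  if (length(unique(values)) == 1L) {
    warning("constant marker values: AUROC is 0.5")
  }
  r <- pROC::roc(response = is_case, predictor = values,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(threshold = r$thresholds,
                    sensitivity = r$sensitivities,
                    fpr = 1 - r$specificities)
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  rownames(pts) <- NULL
  structure(
    list(points = pts, auroc = as.numeric(r$auc),
         n_pos = sum(is_case), n_neg = sum(!is_case),
         values = values, is_case = is_case, .proc = r),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUROC = %.4f (%d cases, %d controls)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated ROC curves (DeLong test)
#'
#' Paired two-sided DeLong test for two markers measured on the same
#' samples.
#'
#' @param a,b `roc_result` objects from [roc_curve()].
#' @param paired Must be `TRUE`; the curves must share their samples.
#' @return Two-sided p-value.
#' @export
compare_roc <- function(a, b, paired = TRUE) {
  if (!paired) stop("only the paired comparison is supported")
  if (a$n_pos != b$n_pos || a$n_neg != b$n_neg ||
      !identical(a$is_case, b$is_case)) {
    stop("paired comparison requires the same samples in both curves")
  }
  if (identical(a$values, b$values)) return(1)
  res <- pROC::roc.test(a$.proc, b$.proc, method = "delong", paired = TRUE)
  unname(res$p.value)
}

#' Combined marker analysis against AFP
#'
#' Cross-tabulates methylation-marker positivity against serum AFP
#' positivity (AFP-positive defined as `afp_ng_ml >= afp_cutoff`) among
#' cases with an AFP measurement, and derives the headline percentages:
#' marker-positive rate, AFP-positive rate, union positivity, the
#' AFP-negative share of marker-positives, and the additional cases the
#' marker detects over AFP alone.
#'
#' @param marker_pos Logical marker calls for the cases.
#' @param afp_ng_ml Serum AFP (ng/mL), same length; `NA` excluded.
#' @param afp_cutoff AFP positivity cutoff (default 20 ng/mL, inclusive).
#' @return List with `n`, `quadrants` (2x2 counts, marker x AFP),
#'   `pct_marker_pos`, `pct_afp_pos`, `pct_union_pos`,
#'   `pct_marker_pos_afp_neg_of_marker_pos`, `pct_additional_over_afp`
#'   (percent scale).
#' @export
combined_marker <- function(marker_pos, afp_ng_ml, afp_cutoff = 20) {
  stopifnot(length(marker_pos) == length(afp_ng_ml))
  keep <- !is.na(afp_ng_ml) & !is.na(marker_pos)
  marker_pos <- marker_pos[keep]; afp <- afp_ng_ml[keep]
  n <- length(marker_pos)
  if (n == 0L) stop("no samples with AFP data")
  afp_pos <- afp >= afp_cutoff
  quadrants <- matrix(
    c(sum(marker_pos & afp_pos), sum(marker_pos & !afp_pos),
      sum(!marker_pos & afp_pos), sum(!marker_pos & !afp_pos)),
    nrow = 2, byrow = TRUE,
    dimnames = list(marker = c("pos", "neg"), afp = c("pos", "neg")))
  n_marker <- sum(marker_pos)
  list(
    n = n, quadrants = quadrants,
    pct_marker_pos = 100 * n_marker / n,
    pct_afp_pos = 100 * sum(afp_pos) / n,
    pct_union_pos = 100 * sum(marker_pos | afp_pos) / n,
    pct_marker_pos_afp_neg_of_marker_pos =
      if (n_marker > 0) 100 * sum(marker_pos & !afp_pos) / n_marker else 0,
    pct_additional_over_afp = 100 * sum(marker_pos & !afp_pos) / n
  )
}

#' Clinicopathological group tests
#'
#' Distribution tests of the quantitative sense-strand marker across
#' clinical subgroups of the cases (Kruskal-Wallis, with stages 2-4 pooled
#' and grades 2-3 pooled because the upper strata are small), Spearman
#' correlation of the marker with AFP, and cohort-balance tests (Student t
#' for age, Fisher exact for sex) between cases and controls.
#'
#' @param cohort Data frame with columns `group`, `age`, `sex`, `hbv`,
#'   `hcv`, `stage`, `grade`, `afp_ng_ml` and `marker_value` (quantitative
#'   sense-strand MSP value); one row per sample. Cases are rows with
#'   `group == "HCC"`.
#' @param afp_cutoff AFP grouping cutoff (default 20 ng/mL).
#' @return Nested list of `{statistic, p}` per test; tests with degenerate
#'   group structure are reported as `NULL` with a warning.
#' @export
group_tests <- function(cohort, afp_cutoff = 20) {
  hcc <- cohort[cohort$group == "HCC", , drop = FALSE]
  kw <- function(value, fac, label) {
    fac <- factor(fac)
    keep <- !is.na(value) & !is.na(fac) & fac != "unknown"
    fac <- droplevels(factor(fac[keep])); value <- value[keep]
    if (nlevels(fac) < 2L || any(table(fac) < 1L)) {
      warning("degenerate groups for ", label, "; test skipped")
      return(NULL)
    }
    res <- stats::kruskal.test(value, fac)
    list(statistic = unname(res$statistic), p = unname(res$p.value))
  }
  stage_group <- ifelse(hcc$stage %in% c("2", "3", "4"), "2-4",
                        as.character(hcc$stage))
  grade_group <- ifelse(hcc$grade %in% c("2", "3"), "2-3",
                        as.character(hcc$grade))
  afp_group <- ifelse(is.na(hcc$afp_ng_ml), "unknown",
                      ifelse(hcc$afp_ng_ml >= afp_cutoff, "pos", "neg"))
  sp <- {
    keep <- !is.na(hcc$afp_ng_ml) & !is.na(hcc$marker_value)
    if (sum(keep) >= 3L) {
      res <- suppressWarnings(
        stats::cor.test(hcc$marker_value[keep], hcc$afp_ng_ml[keep],
                        method = "spearman"))
      list(statistic = unname(res$estimate), p = unname(res$p.value))
    } else NULL
  }
  is_case <- cohort$group == "HCC"
  tt <- if (length(unique(is_case)) == 2L) {
    res <- stats::t.test(cohort$age[is_case], cohort$age[!is_case])
    list(statistic = unname(res$statistic), p = unname(res$p.value))
  } else NULL
  fe <- {
    tab <- table(cohort$sex, is_case)
    if (all(dim(tab) == c(2L, 2L))) {
      res <- stats::fisher.test(tab)
      list(statistic = unname(res$estimate), p = unname(res$p.value))
    } else NULL
  }
  list(
    kruskal_wallis = list(
      stage = kw(hcc$marker_value, stage_group, "stage"),
      grade = kw(hcc$marker_value, grade_group, "grade"),
      hbv = kw(hcc$marker_value, hcc$hbv, "hbv"),
      hcv = kw(hcc$marker_value, hcc$hcv, "hcv"),
      afp_group = kw(hcc$marker_value, afp_group, "afp_group")),
    spearman_marker_afp = sp,
    student_t_age = tt,
    fisher_exact_sex = fe
  )
}
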