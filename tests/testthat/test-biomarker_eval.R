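test_that("density tally counts categories per group and modes differ on missing sites", {
  v <- function(id, g, calls) {
    names(calls) <- seq_along(calls)
    structure(list(sample_id = id, strand = "antisense", calls = calls,
                   conversion_rate = 1, qc_pass = TRUE),
              class = "call_vector")
  }
  vs <- list(v("a", "G1", c("C_ONLY", "T_ONLY", "MISSING", "C_GT_T")),
             v("b", "G1", c("C_ONLY", "C_LE_T", "T_ONLY", "T_ONLY")),
             v("c", "G2", c("T_ONLY", "T_ONLY", "T_ONLY", "T_ONLY")))
  groups <- c("G1", "G1", "G2")

  all_av <- density_tally(vs, groups, mode = "all_available")
  expect_equal(unname(all_av$counts["G1", "C_ONLY"]), 2L)
  expect_equal(unname(all_av$counts["G1", "MISSING"]), 1L)
  # tally conservation: categories + missing = sites x samples
  expect_equal(sum(all_av$counts["G1", ]), 8L)

  cc <- density_tally(vs, groups, mode = "complete_cases")
  expect_equal(cc$sites_used, c(1L, 2L, 4L))  # site 3 missing in sample a
  expect_equal(sum(cc$counts), 9L)

  single <- density_tally(vs[3], "G2")
  expect_equal(unname(single$counts["G2", "T_ONLY"]), 4L)
})

test_that("the printed-count fixture reproduces the published tallies", {
  fx <- printed_density_fixture()
  vectors <- c(fx$HCC, fx$adjacent_non_HCC, fx$control)
  groups <- rep(c("HCC", "adjacent_non_HCC", "control"), c(32, 32, 16))
  fr <- tally_fraction(density_tally(vectors, groups))
  expect_equal(fr$HCC$count, 295L)
  expect_equal(fr$HCC$total, 640L)
  expect_equal(fr$adjacent_non_HCC$count, 29L)
  expect_equal(fr$adjacent_non_HCC$total, 542L)
  expect_equal(fr$control$count, 0L)
  expect_equal(fr$control$total, 295L)
})

test_that("Pearson chi-squared matches the direct formula and handles edge tables", {
  flat <- pearson_chi2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rpois(8, 40) + 1, nrow = 2)
    res <- pearson_chi2(m)
    expect_equal(res$chi2, oracle_chi2(m), tolerance = 1e-10)
    expect_equal(res$df, 3)
    expect_equal(res$p, pchisq(res$chi2, 3, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(pearson_chi2(rbind(c(5, 0), c(5, 0))), "margin")
  expect_error(pearson_chi2(rbind(c(-1, 2), c(3, 4))), "nonnegative")
})

test_that("BSP positivity applies the >=50% detected-site rule", {
  v <- function(calls) {
    names(calls) <- seq_along(calls)
    structure(list(sample_id = "s", strand = "sense", calls = calls,
                   conversion_rate = 1, qc_pass = TRUE),
              class = "call_vector")
  }
  expect_true(bsp_positive(v(rep("C_ONLY", 20))))
  expect_false(bsp_positive(v(rep("T_ONLY", 20))))
  # boundary is inclusive: 10 detected of 20
  expect_true(bsp_positive(v(rep(c("C_LE_T", "T_ONLY"), 10))))
  # 9 of 20 falls short
  expect_false(bsp_positive(v(c(rep("C_GT_T", 9), rep("T_ONLY", 11)))))
  # missing sites drop out of the denominator
  expect_true(bsp_positive(v(c(rep("C_ONLY", 5), rep("T_ONLY", 4),
                               rep("MISSING", 11)))))
  expect_warning(res <- bsp_positive(v(rep("MISSING", 5))), "undefined")
  expect_true(is.na(res))
})

test_that("MSP positivity is the detected flag", {
  expect_true(msp_positive(data.frame(detected = TRUE)))
  expect_false(msp_positive(data.frame(detected = FALSE)))
})

test_that("sensitivity and specificity behave and flip correctly", {
  is_case <- rep(c(TRUE, FALSE), c(20, 30))
  perfect <- sensitivity_specificity(is_case, is_case)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  allneg <- sensitivity_specificity(rep(FALSE, 50), is_case)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)

  set.seed(41)
  calls <- runif(50) < 0.4
  a <- sensitivity_specificity(calls, is_case)
  b <- sensitivity_specificity(!calls, is_case)
  expect_equal(b$sensitivity, 1 - a$sensitivity)
  expect_equal(b$specificity, 1 - a$specificity)
  expect_error(sensitivity_specificity(calls, rep(TRUE, 50)), "classes")
})

test_that("AUROC equals the all-pairs Mann-Whitney statistic", {
  set.seed(43)
  for (i in 1:10) {
    n <- 40
    is_case <- rep(c(TRUE, FALSE), each = n / 2)
    values <- rnorm(n) + is_case * runif(1, 0, 2)
    values[sample(n, 5)] <- round(values[sample(n, 5)])  # inject ties
    r <- roc_curve(values, is_case)
    expect_equal(r$auroc, oracle_auroc(values, is_case), tolerance = 1e-12)
  }
  sep <- roc_curve(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(sep$auroc, 1.0)
  expect_warning(r0 <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5)),
                 "constant")
  expect_equal(r0$auroc, 0.5)
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(47)
  is_case <- rep(c(TRUE, FALSE), each = 25)
  values <- rlnorm(50, meanlog = is_case)
  a <- roc_curve(values, is_case)$auroc
  expect_equal(roc_curve(log(values), is_case)$auroc, a, tolerance = 1e-12)
  expect_equal(roc_curve(rank(values), is_case)$auroc, a, tolerance = 1e-12)
})

test_that("paired DeLong comparison separates informative from noise markers", {
  set.seed(53)
  is_case <- rep(c(TRUE, FALSE), each = 100)
  hits <- 0
  for (i in 1:25) {
    truth <- as.numeric(is_case) + rnorm(200, 0, 0.5)
    noise <- rnorm(200)
    p <- compare_roc(roc_curve(truth, is_case), roc_curve(noise, is_case))
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 24)

  v <- rnorm(200)
  r <- roc_curve(v, is_case)
  expect_equal(compare_roc(r, r), 1)
  a <- roc_curve(v + rnorm(200, 0, 0.2), is_case)
  expect_equal(compare_roc(a, r), compare_roc(r, a), tolerance = 1e-12)
  other <- roc_curve(rnorm(100), rep(c(TRUE, FALSE), each = 50))
  expect_error(compare_roc(r, other), "same samples")
})

test_that("combined-marker quadrants reproduce the published percentages", {
  fx <- combined_marker_fixture()
  res <- combined_marker(fx$marker_pos, fx$afp_ng_ml)
  expect_equal(res$n, 53L)
  expect_equal(res$pct_marker_pos, 100 * 35 / 53)
  expect_equal(res$pct_union_pos, 100 * 44 / 53)
  expect_equal(res$pct_marker_pos_afp_neg_of_marker_pos, 60)
  expect_equal(res$pct_additional_over_afp, 100 * 21 / 53)
  expect_equal(res$pct_afp_pos, 100 * 23 / 53)
  expect_equal(unname(res$quadrants["pos", "pos"]), 14L)

  zero <- combined_marker(rep(FALSE, 10), rep(1, 10))
  expect_equal(zero$pct_marker_pos, 0)
  expect_equal(zero$pct_union_pos, 0)
  expect_error(combined_marker(logical(0), numeric(0)), "AFP")
})

test_that("group tests cover the clinicopathological comparisons", {
  set.seed(59)
  n <- 60
  cohort <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    group = rep(c("HCC", "cirrhosis"), each = n / 2),
    age = rnorm(n, 58, 10), sex = sample(c("M", "F"), n, replace = TRUE),
    hbv = sample(c(TRUE, FALSE), n, replace = TRUE),
    hcv = sample(c(TRUE, FALSE), n, replace = TRUE),
    stage = sample(c("1", "2", "3", "4"), n, replace = TRUE),
    grade = sample(c("1", "2", "3"), n, replace = TRUE),
    afp_ng_ml = rlnorm(n, 2, 1), marker_value = rlnorm(n, 3, 1))
  res <- group_tests(cohort)
  for (t in res$kruskal_wallis) expect_true(is.null(t) || t$p >= 0 && t$p <= 1)
  expect_true(res$student_t_age$p > 0 && res$student_t_age$p <= 1)
  expect_true(res$fisher_exact_sex$p > 0 && res$fisher_exact_sex$p <= 1)

  # perfectly monotone marker vs AFP gives Spearman rho 1
  mono <- cohort
  mono$afp_ng_ml <- seq_len(n)
  mono$marker_value <- (seq_len(n))^2
  expect_equal(group_tests(mono)$spearman_marker_afp$statistic, 1)

  # identical age samples give t statistic 0
  flat <- cohort
  flat$age <- rep(c(50, 60), n / 2)
  expect_equal(group_tests(flat)$student_t_age$statistic, 0, tolerance = 1e-12)
})

test_that("stage test p-values are uniform when stage carries no signal", {
  set.seed(61)
  ps <- replicate(150, {
    n <- 40
    cohort <- data.frame(
      sample_id = sprintf("s%02d", 1:n), group = "HCC",
      age = rnorm(n, 58, 10), sex = "M", hbv = FALSE, hcv = FALSE,
      stage = sample(rep(c("1", "2"), each = n / 2)),
      grade = "1", afp_ng_ml = rlnorm(n, 2, 1),
      marker_value = rlnorm(n, 3, 1))
    suppressWarnings(group_tests(cohort))$kruskal_wallis$stage$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
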