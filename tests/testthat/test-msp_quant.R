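test_that("standard-curve fit recovers slope and efficiency", {
  perfect <- data.frame(copies = c(1e5, 1e4, 1e3),
                        cq = c(15.0, 18.3219, 21.6439))
  cu <- fit_standard_curve(perfect)
  expect_equal(cu$slope, -3.3219, tolerance = 1e-4)
  expect_equal(cu$efficiency, 2.0, tolerance = 1e-4)
  expect_equal(cu$lod_copies, 6)
  expect_gt(cu$r_squared, 0.9999)

  # efficiency from slope alone
  cu3 <- fit_standard_curve(data.frame(copies = c(1e4, 1e3, 1e2),
                                       cq = 40 - 3 * log10(c(1e4, 1e3, 1e2))))
  expect_equal(cu3$efficiency, 10^(1 / 3), tolerance = 1e-6)

  expect_error(fit_standard_curve(perfect[1:2, ]), "3 dilution points")
  expect_error(fit_standard_curve(data.frame(copies = c(10, 10, 10),
                                             cq = c(1, 2, 3))), "variance")
})

test_that("noisy dilution series recover the true slope within 3 SE", {
  set.seed(13)
  true_slope <- -log2(10)
  for (i in 1:20) {
    copies <- rep(10^(5:1), each = 2)
    cq <- 38 + true_slope * log10(copies) + rnorm(length(copies), 0, 0.1)
    cu <- fit_standard_curve(data.frame(copies = copies, cq = cq))
    fit <- lm(cq ~ log10(copies))
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(cu$slope - true_slope), 4 * se)
  }
})

test_that("quantification inverts the curve and applies the LOD", {
  cu <- fit_standard_curve(data.frame(copies = 10^(5:1),
                                      cq = 38 - log2(10) * (5:1)))
  # interpolation identity at a standard point
  q100 <- quantify(38 - log2(10) * 2, cu)
  expect_equal(q100$copies_per_assay, 100, tolerance = 1e-9)
  expect_true(q100$detected)

  nd <- quantify(NA_real_, cu)
  expect_false(nd$detected)
  expect_equal(nd$copies_per_assay, 0)

  cq_5.9 <- cu$intercept + cu$slope * log10(5.9)
  q <- suppressWarnings(quantify(cq_5.9, cu))  # below the lowest standard
  expect_false(q$detected)
  expect_equal(q$copies_per_assay, 0)
  expect_equal(q$copies_raw, 5.9, tolerance = 1e-9)

  expect_warning(quantify(cu$intercept + 5, cu), "calibrated range")
})

test_that("quantify(simulate) round-trips exactly without noise", {
  cu <- fit_standard_curve(data.frame(copies = 10^(5:1),
                                      cq = 38 - log2(10) * (5:1)))
  grid <- 10^seq(log10(6), 6, length.out = 25)
  cq <- simulate_msp(grid, cu, cq_noise_sd = 0, poisson = FALSE)
  q <- suppressWarnings(quantify(cq, cu))
  expect_equal(q$copies_raw, grid, tolerance = 1e-9)

  # efficiency-slope bijection
  for (E in c(1.2, 1.5, 1.8, 2.0)) {
    slope <- -1 / log10(E)
    expect_equal(10^(-1 / slope), E, tolerance = 1e-12)
  }
})

test_that("input normalization and mass conversion use the stated constants", {
  expect_equal(normalize_input(150), 1.0)
  expect_equal(normalize_input(300), 0.5)
  expect_equal(normalize_input(75), 2.0)
  expect_error(normalize_input(0), "positive")

  expect_equal(mass_to_copies(6), 2)      # one diploid cell
  expect_equal(mass_to_copies(0), 0)
  expect_equal(mass_to_copies(450), 150)
  expect_error(mass_to_copies(-1), "nonnegative")
})

test_that("duplicate averaging uses the either-replicate detection rule", {
  mk <- function(value, detected) {
    data.frame(sample_id = "s", assay = "sense", normalized_value = value,
               detected = detected)
  }
  both <- rbind(mk(100, TRUE), mk(100, TRUE))
  expect_equal(average_duplicates(both)$normalized_value, 100)

  mixed <- rbind(mk(0, FALSE), mk(20, TRUE))
  avg <- average_duplicates(mixed)
  expect_equal(avg$normalized_value, 10)
  expect_true(avg$detected)
  expect_false(average_duplicates(mixed, detect_rule = "both")$detected)

  none <- rbind(mk(0, FALSE), mk(0, FALSE))
  expect_equal(average_duplicates(none)$normalized_value, 0)
  expect_false(average_duplicates(none)$detected)

  bad <- rbind(mk(1, TRUE),
               data.frame(sample_id = "t", assay = "sense",
                          normalized_value = 1, detected = TRUE))
  expect_error(average_duplicates(bad), "share")
})

test_that("Poisson sampling drives detection near the limit of detection", {
  cu <- fit_standard_curve(data.frame(copies = 10^(5:1),
                                      cq = 38 - log2(10) * (5:1)))
  set.seed(17)
  det_rate <- function(copies) {
    cq <- simulate_msp(rep(copies, 2000), cu, cq_noise_sd = 0, poisson = TRUE)
    mean(suppressWarnings(quantify(cq, cu))$detected)
  }
  d1 <- det_rate(1); d6 <- det_rate(6); d60 <- det_rate(60)
  expect_lt(d1, d6)
  expect_lt(d6, d60)

  # not-detected frequency at the LOD matches the Poisson zero class
  cq6 <- simulate_msp(rep(6, 10000), cu, cq_noise_sd = 0, poisson = TRUE)
  expect_equal(mean(is.na(cq6)), exp(-6), tolerance = 0.5)
  expect_true(all(is.na(simulate_msp(rep(0, 100), cu))))
})
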