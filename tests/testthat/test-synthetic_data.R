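test_that("reconstituted standards carry the mixing fraction on both strands", {
  s <- toy_setup()
  st <- make_reconstituted_standard(0.25, s$site_map)
  expect_true(all(st$sense == 0.25))
  expect_true(all(st$antisense == 0.25))
  expect_true(all(make_reconstituted_standard(0, s$site_map)$sense == 0))
  expect_true(all(make_reconstituted_standard(1, s$site_map)$antisense == 1))
  expect_error(make_reconstituted_standard(1.2, s$site_map), "\\[0,1\\]")
})

test_that("noiseless traces put the full signal in the expected channel", {
  s <- toy_setup()
  tr <- function(f, strand = "sense") {
    p <- simulate_trace(make_reconstituted_standard(f, s$site_map), strand,
                        s$region, s$site_map, noise_sd = 0,
                        conversion_failure_rate = 0)
    p[p$is_cpg, ]
  }
  full <- tr(1)
  expect_true(all(full$height_C == 100 & full$height_T == 0))
  none <- tr(0)
  expect_true(all(none$height_C == 0 & none$height_T == 100))
  # the chromatogram response is anchored so C and T cross near 10%
  ten <- tr(0.10)
  expect_true(all(ten$height_C > ten$height_T))
  five <- tr(0.05)
  expect_true(all(five$height_C < five$height_T))
  expect_error(simulate_trace(make_reconstituted_standard(1, s$site_map),
                              "sense", s$region, s$site_map, noise_sd = -1),
               "nonnegative")
})

test_that("conversion failures surface as residual C at non-CpG positions", {
  s <- toy_setup()
  st <- make_reconstituted_standard(0, s$site_map)
  p <- simulate_trace(st, "sense", s$region, s$site_map, noise_sd = 0,
                      conversion_failure_rate = 0.10, seed = 71)
  rate <- conversion_efficiency(p)
  expect_lt(rate, 0.95)
  expect_gt(rate, 0.75)
  clean <- simulate_trace(st, "sense", s$region, s$site_map, noise_sd = 0,
                          conversion_failure_rate = 0)
  expect_equal(conversion_efficiency(clean), 1.0)
})

test_that("clone simulation hits its extreme fractions exactly", {
  s <- toy_setup()
  all1 <- simulate_clones(make_reconstituted_standard(1, s$site_map),
                          "antisense", 10, seed = 73)
  expect_true(all(all1$calls == 1))
  expect_equal(all1$clone_count, 10L)
  all0 <- simulate_clones(make_reconstituted_standard(0, s$site_map),
                          "antisense", 10, seed = 73)
  expect_true(all(all0$calls == 0))
})

test_that("cohort generation is deterministic and validates its config", {
  cfg <- default_generator_config(seed = 77)
  cfg$cohort_sizes <- c(HCC = 3L, adjacent_non_HCC = 3L, normal_liver = 2L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$msp, b$msp)
  expect_identical(a$peaks, b$peaks)
  expect_identical(lapply(a$clones, `[[`, "calls"),
                   lapply(b$clones, `[[`, "calls"))

  cfg2 <- cfg; cfg2$seed <- 78L
  expect_false(identical(generate_cohort(cfg2)$msp$cq, a$msp$cq))

  empty <- default_generator_config(seed = 1)
  empty$cohort_sizes[] <- 0L
  out <- generate_cohort(empty)
  expect_equal(nrow(out$samples), 0L)
  expect_equal(nrow(out$msp), 0L)

  bad <- default_generator_config(seed = 1)
  bad$cohort_sizes <- c(liver_of_unknown_kind = 3L)
  expect_error(generate_cohort(bad), "unknown group")
})

test_that("written cohorts are byte-identical across runs with one seed", {
  cfg <- default_generator_config(seed = 79)
  cfg$cohort_sizes <- c(HCC = 2L, normal_liver = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("with all noise off, assay positivity agrees with generator truth", {
  cfg <- default_generator_config(seed = 83)
  cfg$cohort_sizes <- c(HCC = 10L, adjacent_non_HCC = 10L, normal_liver = 4L)
  cfg$qpcr$cq_noise_sd <- 0
  cfg$qpcr$poisson <- FALSE
  cfg$qpcr$input_sdlog <- 0
  cfg$trace$noise_sd <- 0
  cfg$trace$conversion_failure_rate <- 0
  coh <- generate_cohort(cfg, components = "msp")
  rep <- suppressWarnings(evaluate_cohort(coh))
  q <- rep$quant
  truth <- coh$truth
  for (assay in c("sense", "antisense")) {
    got <- q$detected[q$assay == assay][match(truth$sample_id,
                                              q$sample_id[q$assay == assay])]
    expect_equal(got, truth[[paste0("truth_pos_", assay)]], info = assay)
  }
})
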