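#' Default synthetic-cohort generator configuration
#'
#' Encodes the study conditions the pipeline is exercised under: cohort
#' sizes mirroring the MSP study population (58 HCC, 58 matched adjacent
#' non-tumor, 41 cirrhosis, 39 hepatitis, 6 normal liver, plus nonhepatic,
#' fetal and murine negative controls), 30 CpG sites of which 1-20 are
#' analyzable on the antisense read, and the default "liver biology":
#' antisense background methylation in all adult liver groups, sense-strand
#' methylation predominantly in HCC, nothing in nonliver/fetal/mouse
#' tissue.
#'
#' Per group and strand a sample is methylated with probability `prob` and,
#' if so, carries a per-site methylated fraction drawn uniformly from
#' `range` (uniform across sites). The same per-sample fraction drives the
#' chromatogram, clone and MSP readouts, so every assay observes one
#' underlying truth. MSP Cq values are generated from a shared standard
#' curve (efficiency 2, Cq 38 at one copy) with Poisson sampling of
#' template molecules at low copy number; AFP is log-normal with the HCC
#' parameters set so roughly 43% of HCC exceed 20 ng/mL.
#'
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it through one sequential stream.
#' @return An object of class `generator_config` (a nested list; edit
#'   fields directly to change conditions).
#' @export
default_generator_config <- function(seed = 1L) {
  strand_profile <- function(prob, lo, hi) list(prob = prob, range = c(lo, hi))
  biology <- list(
    HCC = list(sense = strand_profile(0.70, 0.20, 0.80),
               antisense = strand_profile(0.75, 0.25, 0.85)),
    adjacent_non_HCC = list(sense = strand_profile(0.15, 0.04, 0.20),
                            antisense = strand_profile(0.60, 0.05, 0.30)),
    normal_liver = list(sense = strand_profile(0.00, 0, 0),
                        antisense = strand_profile(0.83, 0.05, 0.25)),
    hepatitis = list(sense = strand_profile(0.10, 0.04, 0.15),
                     antisense = strand_profile(0.75, 0.05, 0.30)),
    cirrhosis = list(sense = strand_profile(0.17, 0.20, 0.60),
                     antisense = strand_profile(0.50, 0.05, 0.30)),
    nonliver = list(sense = strand_profile(0, 0, 0),
                    antisense = strand_profile(0, 0, 0)),
    fetal_liver = list(sense = strand_profile(0, 0, 0),
                       antisense = strand_profile(0, 0, 0)),
    mouse_liver = list(sense = strand_profile(0, 0, 0),
                       antisense = strand_profile(0, 0, 0))
  )
  demography <- list(
    HCC = list(age_mean = 58.7, age_sd = 11.9, p_male = 39 / 58,
               p_hbv = 30 / 58, p_hcv = 15 / 58,
               afp_meanlog = log(20) - stats::qnorm(0.57) * 2.0,
               afp_sdlog = 2.0),
    adjacent_non_HCC = list(age_mean = 58.7, age_sd = 11.9, p_male = 39 / 58,
                            p_hbv = 30 / 58, p_hcv = 15 / 58,
                            afp_meanlog = log(4), afp_sdlog = 0.8),
    normal_liver = list(age_mean = 64, age_sd = 7.5, p_male = 4 / 6,
                        p_hbv = 0, p_hcv = 0,
                        afp_meanlog = log(4), afp_sdlog = 0.8),
    hepatitis = list(age_mean = 55, age_sd = 11.9, p_male = 19 / 39,
                     p_hbv = 12 / 39, p_hcv = 31 / 39,
                     afp_meanlog = log(4), afp_sdlog = 0.8),
    cirrhosis = list(age_mean = 56, age_sd = 14.4, p_male = 27 / 41,
                     p_hbv = 6 / 41, p_hcv = 22 / 41,
                     afp_meanlog = log(4), afp_sdlog = 0.8),
    nonliver = list(age_mean = 50, age_sd = 15, p_male = 0.5,
                    p_hbv = 0, p_hcv = 0,
                    afp_meanlog = log(4), afp_sdlog = 0.8),
    fetal_liver = list(age_mean = 0, age_sd = 0, p_male = 0.5,
                       p_hbv = 0, p_hcv = 0,
                       afp_meanlog = log(4), afp_sdlog = 0.8),
    mouse_liver = list(age_mean = 0, age_sd = 0, p_male = 0,
                       p_hbv = 0, p_hcv = 0,
                       afp_meanlog = log(4), afp_sdlog = 0.8)
  )
  structure(list(
    seed = as.integer(seed),
    cohort_sizes = c(HCC = 58L, adjacent_non_HCC = 58L, cirrhosis = 41L,
                     hepatitis = 39L, normal_liver = 6L, nonliver = 12L,
                     fetal_liver = 1L, mouse_liver = 3L),
    site_count = 30L,
    analyzed_range_sense = 1:20,
    analyzed_range_antisense = 1:20,
    biology = biology,
    demography = demography,
    stage_probs = c("1" = 28, "2" = 21, "3" = 3, "4" = 1, "unknown" = 5) / 58,
    grade_probs = c("1" = 11, "2" = 33, "3" = 9, "unknown" = 5) / 58,
    trace = list(full_scale = 100, noise_sd = 1,
                 conversion_failure_rate = 0.01),
    clone = list(range = c(7L, 19L),
                 samples_per_group = c(HCC = 4L, adjacent_non_HCC = 4L,
                                       normal_liver = 4L)),
    qpcr = list(slope = -log2(10) * 1, intercept = 38, cq_noise_sd = 0.15,
                poisson = TRUE, lod_copies = 6, input_target = 150,
                input_sdlog = 0.15, dilution_top = 1e5, dilution_points = 6L,
                dilution_replicates = 2L),
    afp_cutoff = 20,
    qc_threshold = 0.95,
    bsp_positivity_threshold = 0.5
  ), class = "generator_config")
}

#' Reconstituted methylation standard
#'
#' Population state of a defined mixture of fully methylated and fully
#' unmethylated bisulfite-converted DNA: every CpG site methylated at the
#' mixing fraction on both strands.
#'
#' @param fraction Methylated fraction in `[0,1]` (the standards used for
#'   calibration are 0, 0.10, 0.25, 0.50 and 1).
#' @param site_map The `cpg_site_map`.
#' @return A [methylation_state()] with fraction values and
#'   `strand_mode = "symmetric"`.
#' @export
make_reconstituted_standard <- function(fraction, site_map) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0,1]")
  methylation_state(site_map, sense = fraction, antisense = fraction,
                    strand_mode = "symmetric")
}

#' Chromatogram C-signal response to the methylated fraction
#'
#' Direct sequencing of a bisulfite PCR product over-represents the
#' methylated (C-retaining) template: the calibration mixtures show the C
#' and T peaks crossing near a 10% methylated fraction and the T peak
#' vanishing by 25%. This monotone response maps the population methylated
#' fraction to the C channel's share of total signal, anchored at those
#' calibration points; it is what makes the peak-comparison reference
#' index recover the calibrated fraction bands.
#'
#' @param fraction Methylated fraction in `[0,1]` (vectorized).
#' @return C-signal share in `[0,1]`.
#' @export
chromatogram_response <- function(fraction) {
  f <- fraction
  s <- ifelse(f < 0.10, 5 * f,
              ifelse(f < 0.25, 0.52 + (f - 0.10) / 0.15 * (0.96 - 0.52),
                     0.96 + (f - 0.25) / 0.75 * 0.04))
  pmin(pmax(s, 0), 1)
}

trunc_noise <- function(x, sd) {
  if (sd == 0) return(x)
  pmax(x + stats::rnorm(length(x), 0, sd), 0)
}

#' Simulate a direct-sequencing peak table
#'
#' Emits one row per reference cytosine of the treated strand (the
#' positions the pipeline reads: CpG cytosines plus the non-CpG cytosines
#' used for conversion QC). At CpG sites the C and T heights follow the
#' population methylated fraction through [chromatogram_response()]; at
#' non-CpG cytosines the signal is all-T except at the configured
#' conversion-failure rate, where the unconverted C is retained.
#' Truncated-at-zero Gaussian noise is added to both channels.
#'
#' @param state A population [methylation_state()] (fractions allowed).
#' @param strand `"sense"` or `"antisense"`.
#' @param region A [reference_region()].
#' @param site_map The `cpg_site_map`.
#' @param noise_sd Peak-height noise SD (same units as `full_scale`).
#' @param conversion_failure_rate Per-position probability that a non-CpG
#'   cytosine escapes conversion.
#' @param full_scale Full-scale peak height (arbitrary units).
#' @param sample_id Sample label.
#' @param seed Optional seed for this call.
#' @return Peak-table data frame with columns `sample_id`, `strand`,
#'   `template_pos`, `ref_base`, `height_C`, `height_T`, `is_cpg`,
#'   `site_index`.
#' @export
simulate_trace <- function(state, strand = c("sense", "antisense"), region,
                           site_map, noise_sd = 1,
                           conversion_failure_rate = 0.01, full_scale = 100,
                           sample_id = "sample", seed = NULL) {
  strand <- match.arg(strand)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(region$sequence)
  if (strand == "sense") {
    chars <- seq_chars(region)
    cpg_pos <- site_map$sense_c_pos
    fracs <- state$sense
  } else {
    chars <- strsplit(reverse_complement(region$sequence), "")[[1]]
    cpg_pos <- L + 1L - site_map$antisense_c_pos
    fracs <- state$antisense
  }
  c_pos <- which(chars == "C")
  is_cpg <- c_pos %in% cpg_pos
  site_index <- rep(NA_integer_, length(c_pos))
  site_index[is_cpg] <- site_map$index[match(c_pos[is_cpg], cpg_pos)]
  share <- numeric(length(c_pos))
  share[is_cpg] <- chromatogram_response(fracs[as.character(site_index[is_cpg])])
  n_non <- sum(!is_cpg)
  share[!is_cpg] <- as.numeric(stats::runif(n_non) < conversion_failure_rate)
  df <- data.frame(
    sample_id = sample_id, strand = strand, template_pos = c_pos,
    ref_base = "C",
    height_C = trunc_noise(full_scale * share, noise_sd),
    height_T = trunc_noise(full_scale * (1 - share), noise_sd),
    is_cpg = is_cpg, site_index = site_index, stringsAsFactors = FALSE
  )
  df
}

#' Simulate a clone call matrix
#'
#' Each clone derives from one molecule: per site, methylated with the
#' population fraction as success probability, independently across sites
#' and clones.
#'
#' @param state A population [methylation_state()].
#' @param strand Strand the clones were made from.
#' @param n_clones Number of clones.
#' @param site_subset Site indices covered by the cloned amplicon.
#' @param sample_id Sample label.
#' @param seed Optional seed.
#' @return A [clone_call_matrix()].
#' @export
simulate_clones <- function(state, strand = "antisense", n_clones,
                            site_subset = as.integer(names(state[[strand]])),
                            sample_id = "sample", seed = NULL) {
  stopifnot(n_clones >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fracs <- state[[strand]][as.character(site_subset)]
  m <- matrix(stats::rbinom(n_clones * length(fracs), 1L,
                            rep(fracs, each = n_clones)),
              nrow = n_clones,
              dimnames = list(NULL, site_subset))
  clone_call_matrix(m, sample_id = sample_id, strand = strand)
}

#' Simulate quantitative MSP Cq values
#'
#' The number of amplifiable template molecules is drawn
#' `Poisson(true_copies)` (the dominant stochasticity near the limit of
#' detection); zero templates yield a not-detected reaction (`NA` Cq),
#' otherwise the Cq lies on the standard curve at the template count plus
#' Gaussian cycle noise.
#'
#' @param true_copies Expected methylated template copies per reaction
#'   (vectorized over reactions).
#' @param curve A [standard_curve()] (or any list with `slope` and
#'   `intercept`).
#' @param cq_noise_sd Cq noise SD in cycles.
#' @param poisson Draw template counts Poisson; when `FALSE` the expected
#'   copies are used directly (zero still yields ND).
#' @param seed Optional seed.
#' @return Numeric Cq vector with `NA` for not-detected reactions.
#' @export
simulate_msp <- function(true_copies, curve, cq_noise_sd = 0.15,
                         poisson = TRUE, seed = NULL) {
  stopifnot(all(true_copies >= 0))
  if (!is.null(seed)) set.seed(seed)
  templates <- if (poisson) stats::rpois(length(true_copies), true_copies)
               else true_copies
  cq <- rep(NA_real_, length(templates))
  pos <- templates > 0
  cq[pos] <- curve$intercept + curve$slope * log10(templates[pos])
  if (cq_noise_sd > 0) {
    cq[pos] <- cq[pos] + stats::rnorm(sum(pos), 0, cq_noise_sd)
  }
  cq
}

#' Simulate a serial-dilution standard series
#'
#' Ten-fold dilutions from `top` copies down, `points` levels with
#' `replicates` reactions each, Cq on the configured curve plus noise
#' (no Poisson sampling at these copy numbers).
#'
#' @param assay_id Assay label.
#' @param qpcr The `qpcr` block of a [default_generator_config()].
#' @return Data frame `assay_id`, `copies`, `cq`.
#' @export
simulate_dilution_series <- function(assay_id, qpcr) {
  copies <- rep(qpcr$dilution_top / 10^(seq_len(qpcr$dilution_points) - 1L),
                each = qpcr$dilution_replicates)
  cq <- qpcr$intercept + qpcr$slope * log10(copies) +
    stats::rnorm(length(copies), 0, qpcr$cq_noise_sd)
  data.frame(assay_id = assay_id, copies = copies, cq = cq,
             stringsAsFactors = FALSE)
}

draw_strand_truth <- function(profile) {
  if (stats::runif(1) < profile$prob) {
    stats::runif(1, profile$range[1], profile$range[2])
  } else 0
}

#' Generate a complete synthetic cohort
#'
#' Produces a sample sheet, per-sample truth records, dilution series,
#' duplicate MSP measurements (marker assays plus the BS-actin input
#' assay), and optionally direct-sequencing peak tables and clone call
#' matrices, all deterministic given `config$seed` (a single sequential
#' random stream seeded once at entry).
#'
#' One latent methylated fraction per sample and strand drives every
#' readout: the chromatogram C/T signal, the clone calls, and the expected
#' MSP template count (`fraction x actual input copies`).
#'
#' @param config A [default_generator_config()].
#' @param components Which readouts to generate; the sample sheet, truth
#'   and MSP tables are always produced.
#' @param region,site_map Reference region and site map (default: the
#'   packaged toy promoter).
#' @return List with `samples`, `truth`, `dilutions`, `msp`, and (when
#'   requested) `peaks` and `clones`; plus the `config`, `region` and
#'   `site_map` used.
#' @export
generate_cohort <- function(config = default_generator_config(),
                            components = c("traces", "clones"),
                            region = toy_region(),
                            site_map = enumerate_cpg_sites(region)) {
  stopifnot(inherits(config, "generator_config"))
  bad <- setdiff(names(config$cohort_sizes), names(config$biology))
  if (length(bad) > 0L) stop("unknown group(s) in cohort_sizes: ",
                             paste(bad, collapse = ","))
  set.seed(config$seed)
  qp <- config$qpcr
  dilutions <- do.call(rbind, lapply(c("sense", "antisense", "bs_actin"),
                                     simulate_dilution_series, qpcr = qp))
  truth_curve <- list(slope = qp$slope, intercept = qp$intercept)

  samples <- list(); truth <- list(); msp <- list()
  peaks <- list(); clones <- list()
  clone_quota <- config$clone$samples_per_group

  for (group in names(config$cohort_sizes)) {
    n <- config$cohort_sizes[[group]]
    if (n == 0L) next
    bio <- config$biology[[group]]
    dem <- config$demography[[group]]
    abbrev <- c(HCC = "HCC", adjacent_non_HCC = "ADJ", cirrhosis = "CIR",
                hepatitis = "HEP", normal_liver = "NL", nonliver = "NLV",
                fetal_liver = "FL", mouse_liver = "ML")
    for (k in seq_len(n)) {
      sid <- sprintf("%s_%02d", abbrev[[group]], k)
      frac_s <- draw_strand_truth(bio$sense)
      frac_a <- draw_strand_truth(bio$antisense)
      afp <- stats::rlnorm(1, dem$afp_meanlog, dem$afp_sdlog)
      is_hcc <- group == "HCC"
      samples[[sid]] <- data.frame(
        sample_id = sid, group = group,
        age = round(stats::rnorm(1, dem$age_mean, dem$age_sd), 1),
        sex = if (stats::runif(1) < dem$p_male) "M" else "F",
        hbv = stats::runif(1) < dem$p_hbv,
        hcv = stats::runif(1) < dem$p_hcv,
        stage = if (is_hcc) sample(names(config$stage_probs), 1,
                                   prob = config$stage_probs) else "unknown",
        grade = if (is_hcc) sample(names(config$grade_probs), 1,
                                   prob = config$grade_probs) else "unknown",
        afp_ng_ml = if (group %in% c("mouse_liver", "fetal_liver"))
          NA_real_ else round(afp, 2),
        tumor_size_cm = if (is_hcc)
          round(stats::rlnorm(1, log(5), 0.5), 1) else NA_real_,
        stringsAsFactors = FALSE
      )
      # actual bisulfite-converted input per reaction, targeted at 150 copies
      input_actual <- stats::rlnorm(1, log(qp$input_target), qp$input_sdlog)
      truth[[sid]] <- data.frame(
        sample_id = sid, group = group,
        frac_sense = frac_s, frac_antisense = frac_a,
        true_copies_sense = frac_s * input_actual,
        true_copies_antisense = frac_a * input_actual,
        input_actual = input_actual,
        truth_pos_sense = frac_s * input_actual >= qp$lod_copies,
        truth_pos_antisense = frac_a * input_actual >= qp$lod_copies,
        stringsAsFactors = FALSE
      )
      true_copies <- c(sense = frac_s * input_actual,
                       antisense = frac_a * input_actual,
                       bs_actin = input_actual)
      for (assay in names(true_copies)) {
        cq <- simulate_msp(rep(true_copies[[assay]], 2L), truth_curve,
                           cq_noise_sd = qp$cq_noise_sd, poisson = qp$poisson)
        msp[[paste(sid, assay)]] <- data.frame(
          sample_id = sid, assay = assay, replicate = 1:2, cq = cq,
          stringsAsFactors = FALSE)
      }
      state <- methylation_state(site_map, sense = frac_s, antisense = frac_a)
      if ("traces" %in% components) {
        for (strand in c("sense", "antisense")) {
          peaks[[paste(sid, strand)]] <- simulate_trace(
            state, strand, region, site_map,
            noise_sd = config$trace$noise_sd,
            conversion_failure_rate = config$trace$conversion_failure_rate,
            full_scale = config$trace$full_scale, sample_id = sid)
        }
      }
      if ("clones" %in% components && group %in% names(clone_quota) &&
          k <= clone_quota[[group]]) {
        n_clones <- sample(seq(config$clone$range[1], config$clone$range[2]), 1)
        clones[[sid]] <- simulate_clones(
          state, "antisense", n_clones,
          site_subset = config$analyzed_range_antisense, sample_id = sid)
      }
    }
  }
  bind <- function(lst, template) {
    if (length(lst) == 0L) return(template[0, , drop = FALSE])
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  sample_template <- data.frame(
    sample_id = character(), group = character(), age = numeric(),
    sex = character(), hbv = logical(), hcv = logical(), stage = character(),
    grade = character(), afp_ng_ml = numeric(), tumor_size_cm = numeric())
  truth_template <- data.frame(
    sample_id = character(), group = character(), frac_sense = numeric(),
    frac_antisense = numeric(), true_copies_sense = numeric(),
    true_copies_antisense = numeric(), input_actual = numeric(),
    truth_pos_sense = logical(), truth_pos_antisense = logical())
  msp_template <- data.frame(sample_id = character(), assay = character(),
                             replicate = integer(), cq = numeric())
  out <- list(
    samples = bind(samples, sample_template),
    truth = bind(truth, truth_template),
    dilutions = dilutions,
    msp = bind(msp, msp_template),
    config = config, region = region, site_map = site_map
  )
  if ("traces" %in% components) {
    out$peaks <- bind(peaks, data.frame(
      sample_id = character(), strand = character(), template_pos = integer(),
      ref_base = character(), height_C = numeric(), height_T = numeric(),
      is_cpg = logical(), site_index = integer()))
  }
  if ("clones" %in% components) out$clones <- clones
  out
}
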