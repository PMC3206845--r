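#' @title Tab-separated readers and writers for the pipeline's interchange
#'   formats
#' @description All tables are UTF-8 TSV with a header row. Peak tables:
#'   `sample_id, strand, template_pos, ref_base, height_C, height_T,
#'   is_cpg, site_index`. Call vectors: `sample_id, strand, qc_pass,
#'   conversion_rate`, then one column per site (`x` = missing). Clone
#'   matrices: `sample_id, strand, clone_id`, then one column per site
#'   (`1/0/NA`). MSP measurements: `sample_id, assay, replicate, cq`
#'   (empty = not detected). Dilutions: `assay_id, copies, cq`.
#' @name strandmeth-io
NULL

read_tsv_ <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname strandmeth-io
#' @param path File path.
#' @return `read_peak_table()`: peak-table data frame.
#' @export
read_peak_table <- function(path) {
  df <- read_tsv_(path)
  df$is_cpg <- as.logical(df$is_cpg)
  df$site_index <- suppressWarnings(as.integer(df$site_index))
  df
}

#' @rdname strandmeth-io
#' @param peaks Peak-table data frame.
#' @export
write_peak_table <- function(peaks, path) {
  peaks$height_C <- round(peaks$height_C, 2)
  peaks$height_T <- round(peaks$height_T, 2)
  write_tsv_(peaks, path)
}

#' @rdname strandmeth-io
#' @param vectors List of `call_vector` objects.
#' @export
write_call_vectors <- function(vectors, path) {
  rows <- lapply(vectors, function(v) {
    calls <- v$calls
    calls[calls == "MISSING"] <- "x"
    cbind(data.frame(sample_id = v$sample_id, strand = v$strand,
                     qc_pass = v$qc_pass,
                     conversion_rate = round(v$conversion_rate, 6)),
          as.data.frame(as.list(calls), check.names = FALSE))
  })
  write_tsv_(do.call(rbind, rows), path)
}

#' @rdname strandmeth-io
#' @return `read_call_vectors()`: list of `call_vector` objects.
#' @export
read_call_vectors <- function(path) {
  df <- read_tsv_(path)
  site_cols <- setdiff(names(df), c("sample_id", "strand", "qc_pass",
                                    "conversion_rate"))
  lapply(seq_len(nrow(df)), function(i) {
    calls <- unlist(df[i, site_cols, drop = FALSE])
    calls[calls == "x" | is.na(calls)] <- "MISSING"
    names(calls) <- site_cols
    structure(
      list(sample_id = df$sample_id[i], strand = df$strand[i],
           calls = calls, conversion_rate = df$conversion_rate[i],
           qc_pass = as.logical(df$qc_pass[i])),
      class = "call_vector")
  })
}

#' @rdname strandmeth-io
#' @param clones List of [clone_call_matrix()] objects.
#' @export
write_clone_matrices <- function(clones, path) {
  rows <- lapply(clones, function(m) {
    cbind(data.frame(sample_id = m$sample_id, strand = m$strand,
                     clone_id = seq_len(nrow(m$calls))),
          as.data.frame(m$calls, check.names = FALSE))
  })
  write_tsv_(do.call(rbind, rows), path)
}

#' @rdname strandmeth-io
#' @return `read_clone_matrices()`: named list of [clone_call_matrix()].
#' @export
read_clone_matrices <- function(path) {
  df <- read_tsv_(path)
  site_cols <- setdiff(names(df), c("sample_id", "strand", "clone_id"))
  out <- lapply(split(df, df$sample_id), function(d) {
    clone_call_matrix(as.matrix(d[site_cols]), sample_id = d$sample_id[1],
                      strand = d$strand[1])
  })
  out[unique(df$sample_id)]
}

#' @rdname strandmeth-io
#' @return `read_msp_measurements()`: data frame with `NA` Cq for
#'   not-detected reactions.
#' @export
read_msp_measurements <- function(path) {
  df <- read_tsv_(path)
  df$cq <- suppressWarnings(as.numeric(df$cq))
  df
}

#' @rdname strandmeth-io
#' @param curve A [standard_curve()].
#' @export
write_standard_curve <- function(curve, path) {
  jsonlite::write_json(unclass(curve)[c("slope", "intercept", "efficiency",
                                        "r_squared", "lod_copies")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a generated cohort to a directory of interchange files
#'
#' Emits `samples.tsv`, `truth.tsv`, `dilutions.tsv`, `msp.tsv` and, when
#' present, `peaks.tsv`, `clones.tsv` and `region.fasta`/`site_map.tsv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_(cohort$samples, p("samples.tsv"))
  tr <- cohort$truth
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], function(x) round(x, 6))
  write_tsv_(tr, p("truth.tsv"))
  d <- cohort$dilutions; d$cq <- round(d$cq, 4)
  write_tsv_(d, p("dilutions.tsv"))
  m <- cohort$msp; m$cq <- round(m$cq, 4)
  write_tsv_(m, p("msp.tsv"))
  if (!is.null(cohort$peaks)) write_peak_table(cohort$peaks, p("peaks.tsv"))
  if (!is.null(cohort$clones)) write_clone_matrices(cohort$clones, p("clones.tsv"))
  write_region_fasta(cohort$region, p("region.fasta"))
  write_site_map(cohort$site_map, p("site_map.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List in the shape of a [generate_cohort()] result (without
#'   `config`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  region <- read_region_fasta(p("region.fasta"))
  out <- list(
    samples = read_tsv_(p("samples.tsv")),
    truth = if (file.exists(p("truth.tsv"))) read_tsv_(p("truth.tsv")),
    dilutions = read_tsv_(p("dilutions.tsv")),
    msp = read_msp_measurements(p("msp.tsv")),
    region = region,
    site_map = enumerate_cpg_sites(region)
  )
  out$samples$stage <- as.character(out$samples$stage)
  out$samples$grade <- as.character(out$samples$grade)
  if (file.exists(p("peaks.tsv"))) out$peaks <- read_peak_table(p("peaks.tsv"))
  if (file.exists(p("clones.tsv"))) out$clones <- read_clone_matrices(p("clones.tsv"))
  out
}
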