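#' Construct a reference promoter region
#'
#' A `reference_region` holds a single promoter/first-exon sequence together
#' with its coordinates in the source record. Coordinates are 1-based
#' inclusive; the sequence is normalized to uppercase and restricted to the
#' alphabet `A,C,G,T,N`.
#'
#' @param sequence Nucleotide string (case-insensitive).
#' @param accession_id Source record identifier.
#' @param start_coord,end_coord 1-based inclusive coordinates of the region in
#'   the source record. Defaults to `1..nchar(sequence)`.
#' @param description Free-text description.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(sequence, accession_id = "toy",
                             start_coord = 1L,
                             end_coord = start_coord + nchar(sequence) - 1L,
                             description = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- toupper(sequence)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","))
  }
  if (end_coord - start_coord + 1L != nchar(seq)) {
    stop("end_coord - start_coord + 1 must equal sequence length")
  }
  structure(
    list(accession_id = accession_id, sequence = seq,
         start_coord = as.integer(start_coord),
         end_coord = as.integer(end_coord),
         description = description),
    class = "reference_region"
  )
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("reference_region %s:%d-%d (%d nt)\n", x$accession_id,
              x$start_coord, x$end_coord, nchar(x$sequence)))
  invisible(x)
}

seq_chars <- function(region) strsplit(region$sequence, "")[[1]]

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`.
#'
#' @param seq Nucleotide string over `A,C,G,T,N`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[chars], collapse = "")
}

#' Enumerate and number CpG sites in a window
#'
#' Scans the sense strand of `region` for `CG` dinucleotides whose C lies in
#' `[window_start, window_end - 1]` and numbers them consecutively from 1 in
#' the sense 5' to 3' direction. Each site has a cytosine on both strands:
#' the sense C at `sense_c_pos` and the antisense C paired with the G at
#' `sense_c_pos + 1`. Site numbering always follows the sense strand, also
#' when the antisense strand is analyzed.
#'
#' Dinucleotides containing `N` are skipped with a warning.
#'
#' @param region A [reference_region()].
#' @param window_start,window_end 1-based inclusive window on the region.
#' @return A `cpg_site_map`: data frame with columns `index`, `sense_c_pos`,
#'   `antisense_c_pos` (all region-local 1-based sense coordinates).
#' @export
enumerate_cpg_sites <- function(region, window_start = 1L,
                                window_end = nchar(region$sequence)) {
  L <- nchar(region$sequence)
  if (window_start < 1L || window_end > L || window_start > window_end) {
    stop("window [", window_start, ",", window_end, "] outside region 1..", L)
  }
  chars <- seq_chars(region)
  pos <- seq.int(window_start, max(window_start, window_end - 1L))
  is_cg <- chars[pos] == "C" & chars[pos + 1L] == "G"
  has_n <- chars[pos] == "N" | chars[pos + 1L] == "N"
  if (any(has_n)) {
    warning(sum(has_n), " dinucleotide(s) containing N skipped in CpG scan")
  }
  cpos <- pos[is_cg & !has_n]
  map <- data.frame(
    index = seq_along(cpos),
    sense_c_pos = as.integer(cpos),
    antisense_c_pos = as.integer(cpos + 1L)
  )
  class(map) <- c("cpg_site_map", "data.frame")
  map
}

#' Build a per-molecule methylation state
#'
#' Binary methylation flags per CpG site and strand for a single molecule
#' (or a population when fractions are supplied; fraction-valued states are
#' accepted here but rejected by [bisulfite_convert()], which operates on
#' single molecules).
#'
#' @param site_map A `cpg_site_map`.
#' @param sense,antisense Logical (or fraction in `[0,1]`) vectors, either
#'   length 1 (recycled) or one value per site, or a named vector keyed by
#'   site index.
#' @param strand_mode One of `"symmetric"`, `"sense_only"`,
#'   `"antisense_only"`, `"independent"`; metadata describing how the state
#'   was built.
#' @return An object of class `methylation_state` with numeric per-site
#'   vectors `sense` and `antisense` (0/1 flags or fractions).
#' @export
methylation_state <- function(site_map, sense = 0, antisense = 0,
                              strand_mode = c("independent", "symmetric",
                                              "sense_only", "antisense_only")) {
  strand_mode <- match.arg(strand_mode)
  n <- nrow(site_map)
  expand <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(what, " must have length 1 or ", n)
    if (any(x < 0 | x > 1)) stop(what, " values must lie in [0,1]")
    names(x) <- site_map$index
    x
  }
  structure(
    list(sense = expand(sense, "sense"),
         antisense = expand(antisense, "antisense"),
         strand_mode = strand_mode),
    class = "methylation_state"
  )
}

state_is_binary <- function(state) {
  all(c(state$sense, state$antisense) %in% c(0, 1))
}

#' In-silico bisulfite conversion of one strand
#'
#' Applies the bisulfite rule to a single molecule: every cytosine that is
#' not a methylated CpG cytosine on the treated strand is deaminated and
#' read as T; methylated CpG cytosines are retained as C. The two strands
#' are treated independently. For `strand = "antisense"` the conversion
#' operates on the reverse complement of the sense sequence; the CpG
#' cytosines of that strand are the partners of the sense-strand Gs, and
#' calls are reported against sense-strand site numbers throughout.
#'
#' @param region A [reference_region()].
#' @param strand `"sense"` or `"antisense"`.
#' @param state A [methylation_state()] with binary flags (a population
#'   fraction state is an error; populations are handled by the synthetic
#'   generator).
#' @param site_map The `cpg_site_map` the state refers to.
#' @return A `bisulfite_template`: list with `strand`, `converted_sequence`
#'   (written 5' to 3' of the treated strand), `length`, and `site_template_pos`
#'   (template coordinate of each CpG cytosine, named by site index).
#' @export
bisulfite_convert <- function(region, strand = c("sense", "antisense"),
                              state, site_map) {
  strand <- match.arg(strand)
  if (!inherits(state, "methylation_state")) stop("state must be a methylation_state")
  if (!state_is_binary(state)) {
    stop("bisulfite_convert operates on single molecules: ",
         "methylation flags must be binary, not fractions")
  }
  L <- nchar(region$sequence)
  if (strand == "sense") {
    chars <- seq_chars(region)
    meth_pos <- site_map$sense_c_pos[state$sense[as.character(site_map$index)] == 1]
    site_pos <- site_map$sense_c_pos
  } else {
    chars <- strsplit(reverse_complement(region$sequence), "")[[1]]
    # antisense C partnered with the sense G at sense_c_pos + 1 sits at
    # template coordinate L + 1 - (sense_c_pos + 1)
    all_pos <- L + 1L - site_map$antisense_c_pos
    meth_pos <- all_pos[state$antisense[as.character(site_map$index)] == 1]
    site_pos <- all_pos
  }
  is_c <- chars == "C"
  keep <- rep(FALSE, L)
  keep[meth_pos] <- TRUE
  chars[is_c & !keep] <- "T"
  names(site_pos) <- site_map$index
  structure(
    list(strand = strand,
         converted_sequence = paste(chars, collapse = ""),
         length = L,
         site_template_pos = site_pos),
    class = "bisulfite_template"
  )
}

#' Flag CpG sites rendered unreadable by a homopolymer-T run
#'
#' Long poly-T stretches produced by bisulfite conversion exhaust the
#' sequencing polymerase's ability to keep register, so everything
#' downstream of such a run in the reading direction is lost. Reads are
#' taken in the orientation that visits CpG sites in ascending sense-strand
#' order (for either strand), so "downstream" means higher site numbers.
#'
#' @param template A `bisulfite_template`.
#' @param site_map The `cpg_site_map`.
#' @param min_run_length Minimum poly-T run length that breaks the read
#'   (default 16).
#' @return Integer vector of unreadable site indices (possibly empty).
#' @export
flag_unreadable_sites <- function(template, site_map, min_run_length = 16L) {
  stopifnot(min_run_length >= 2L)
  chars <- strsplit(template$converted_sequence, "")[[1]]
  r <- rle(chars == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- r$values & r$lengths >= min_run_length
  if (!any(qual)) return(integer(0))
  # read position of each site along the template, in the orientation that
  # visits sites in ascending index order; a run is entered at its
  # first-encountered base in that orientation
  tpos <- template$site_template_pos
  if (template$strand == "antisense") {
    read_site <- template$length + 1L - tpos
    read_runs <- template$length + 1L - ends[qual]
  } else {
    read_site <- tpos
    read_runs <- starts[qual]
  }
  flagged <- site_map$index[read_site > min(read_runs)]
  as.integer(sort(flagged))
}

#' Read a reference region from a FASTA file
#'
#' Single-record FASTA. If the description line is formatted
#' `accession:start-end`, the accession and coordinates are parsed from it;
#' otherwise the first word is the accession and coordinates default to
#' `1..length`.
#'
#' @param path FASTA file path.
#' @return A [reference_region()].
#' @export
read_region_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_i <- grep("^>", lines)
  if (length(hdr_i) != 1L) stop("expected exactly one FASTA record in ", path)
  hdr <- sub("^>", "", lines[hdr_i])
  seq <- paste(lines[-hdr_i], collapse = "")
  token <- strsplit(hdr, "\\s+")[[1]][1]
  m <- regmatches(token, regexec("^([^:]+):(\\d+)-(\\d+)$", token))[[1]]
  if (length(m) == 4L) {
    reference_region(seq, accession_id = m[2],
                     start_coord = as.integer(m[3]),
                     end_coord = as.integer(m[4]),
                     description = hdr)
  } else {
    reference_region(seq, accession_id = token, description = hdr)
  }
}

#' Write a reference region to FASTA
#'
#' @param region A [reference_region()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(region, path, width = 70L) {
  hdr <- sprintf(">%s:%d-%d %s", region$accession_id, region$start_coord,
                 region$end_coord, region$description)
  seq <- region$sequence
  starts <- seq.int(1L, nchar(seq), by = width)
  body <- substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
  writeLines(c(trimws(hdr)), path)
  cat(body, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Export a CpG site map as TSV
#'
#' Columns `index`, `sense_c_pos`, `antisense_c_pos`.
#'
#' @param site_map A `cpg_site_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_map <- function(site_map, path) {
  utils::write.table(as.data.frame(site_map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
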