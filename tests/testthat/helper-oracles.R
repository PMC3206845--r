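# Independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals.

# brute-force dinucleotide scan
oracle_cpg_positions <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- integer(0)
  for (p in seq_len(length(chars) - 1L)) {
    if (chars[p] == "C" && chars[p + 1L] == "G") out <- c(out, p)
  }
  out
}

# direct-formula Pearson chi-squared
oracle_chi2 <- function(m) {
  m <- as.matrix(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# all-pairs Mann-Whitney AUROC with half credit for ties
oracle_auroc <- function(values, is_case) {
  pos <- values[is_case]; neg <- values[!is_case]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

toy_setup <- function() {
  region <- toy_region()
  list(region = region, site_map = enumerate_cpg_sites(region))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
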