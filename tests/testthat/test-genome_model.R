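test_that("CpG enumeration finds and numbers CG dinucleotides in sense order", {
  r <- reference_region("ACGTCGA")
  map <- enumerate_cpg_sites(r)
  expect_equal(map$index, c(1L, 2L))
  expect_equal(map$sense_c_pos, c(2L, 5L))
  expect_equal(map$antisense_c_pos, c(3L, 6L))

  expect_equal(nrow(enumerate_cpg_sites(reference_region("ATTTAAG"))), 0L)
  expect_error(enumerate_cpg_sites(r, 0, 7), "outside")
  expect_error(enumerate_cpg_sites(r, 1, 8), "outside")
  expect_warning(enumerate_cpg_sites(reference_region("ACNGT")), "N")
})

test_that("CpG enumeration agrees with a brute-force scan on random sequences", {
  set.seed(11)
  for (i in 1:100) {
    seq <- random_dna(1000)
    map <- enumerate_cpg_sites(reference_region(seq))
    expect_equal(map$sense_c_pos, oracle_cpg_positions(seq))
  }
})

test_that("strand pairing holds for every site", {
  s <- toy_setup()
  expect_equal(s$site_map$antisense_c_pos, s$site_map$sense_c_pos + 1L)
  chars <- strsplit(s$region$sequence, "")[[1]]
  expect_true(all(chars[s$site_map$sense_c_pos] == "C"))
  expect_true(all(chars[s$site_map$antisense_c_pos] == "G"))
})

test_that("bisulfite conversion follows the methylation-dependent C rule", {
  r <- reference_region("ACGA")
  map <- enumerate_cpg_sites(r)
  unmeth <- methylation_state(map, sense = 0, antisense = 0)
  meth <- methylation_state(map, sense = 1, antisense = 1)

  expect_equal(bisulfite_convert(r, "sense", unmeth, map)$converted_sequence,
               "ATGA")
  expect_equal(bisulfite_convert(r, "sense", meth, map)$converted_sequence,
               "ACGA")
  # reverse complement of ACGA is TCGT; its CpG C converts when unmethylated
  expect_equal(
    bisulfite_convert(r, "antisense", unmeth, map)$converted_sequence, "TTGT")
  expect_equal(
    bisulfite_convert(r, "antisense", meth, map)$converted_sequence, "TCGT")

  frac <- methylation_state(map, sense = 0.5)
  expect_error(bisulfite_convert(r, "sense", frac, map), "binary")
})

test_that("fully methylated conversion preserves exactly the CpG-strand Cs", {
  s <- toy_setup()
  meth <- methylation_state(s$site_map, sense = 1, antisense = 1)
  unmeth <- methylation_state(s$site_map, sense = 0, antisense = 0)
  for (strand in c("sense", "antisense")) {
    conv <- bisulfite_convert(s$region, strand, meth, s$site_map)
    chars <- strsplit(conv$converted_sequence, "")[[1]]
    expect_equal(sort(which(chars == "C")), sort(unname(conv$site_template_pos)))
    conv0 <- bisulfite_convert(s$region, strand, unmeth, s$site_map)
    expect_false(grepl("C", conv0$converted_sequence))
  }
})

test_that("conversion is idempotent on an already-converted template", {
  s <- toy_setup()
  set.seed(5)
  flags <- rbinom(nrow(s$site_map), 1, 0.5)
  st <- methylation_state(s$site_map, sense = flags)
  once <- bisulfite_convert(s$region, "sense", st, s$site_map)
  r2 <- reference_region(once$converted_sequence)
  map2 <- enumerate_cpg_sites(r2)
  # surviving CpGs are exactly the methylated ones; convert again methylated
  expect_equal(map2$sense_c_pos, s$site_map$sense_c_pos[flags == 1])
  st2 <- methylation_state(map2, sense = 1)
  twice <- bisulfite_convert(r2, "sense", st2, map2)
  expect_equal(twice$converted_sequence, once$converted_sequence)
})

test_that("poly-T runs truncate the read downstream in site order", {
  s <- toy_setup()
  unmeth <- methylation_state(s$site_map, sense = 0, antisense = 0)
  anti <- bisulfite_convert(s$region, "antisense", unmeth, s$site_map)
  expect_equal(flag_unreadable_sites(anti, s$site_map), 21:30)
  sense <- bisulfite_convert(s$region, "sense", unmeth, s$site_map)
  expect_equal(flag_unreadable_sites(sense, s$site_map), integer(0))
  # below-threshold runs do not truncate
  expect_equal(flag_unreadable_sites(anti, s$site_map, min_run_length = 18L),
               integer(0))
  expect_error(flag_unreadable_sites(anti, s$site_map, min_run_length = 1L))
})

test_that("FASTA and site-map round trips preserve the region", {
  s <- toy_setup()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_region_fasta(s$region, path)
  back <- read_region_fasta(path)
  expect_equal(back$sequence, s$region$sequence)
  expect_equal(back$accession_id, s$region$accession_id)
  expect_equal(back$start_coord, s$region$start_coord)

  shipped <- read_region_fasta(
    system.file("extdata", "toy_promoter.fasta", package = "strandmeth"))
  expect_equal(shipped$sequence, s$region$sequence)

  smp <- withr::local_tempfile(fileext = ".tsv")
  write_site_map(s$site_map, smp)
  expect_equal(read.delim(smp)$sense_c_pos, s$site_map$sense_c_pos)
})
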