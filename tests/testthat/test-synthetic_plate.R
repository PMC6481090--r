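test_that("simulated alleles reflect the requested outcome", {
  locus <- toy_locus()
  set.seed(131)
  expect_identical(simulate_allele(locus, "WT"), locus$reference_amplicon)
  hdr <- simulate_allele(locus, "HDR")
  d <- which(strsplit(hdr, "")[[1]] !=
             strsplit(locus$reference_amplicon, "")[[1]])
  expect_identical(d, as.integer(locus$donor_diffs$pos + 1L))
  expect_identical(substr(hdr, d, d), locus$donor_diffs$alt)
  for (i in 1:20) {
    ind <- simulate_allele(locus, "NHEJ_indel")
    expect_false(nchar(ind) == nchar(locus$reference_amplicon))
  }
  cx <- simulate_allele(locus, "complex")
  expect_gt(nchar(cx), nchar(locus$reference_amplicon))
  # HDR without a donor specification is a configuration error
  expect_error(simulate_allele(toy_locus(donor = FALSE), "HDR"),
               "donor_diffs")
})

test_that("indel sizes follow the configured geometric mean", {
  set.seed(141)
  sizes <- replicate(10000, ampliwell:::sample_indel_size(3))
  expect_lt(abs(mean(sizes) - 3) / 3, 0.05)
  expect_true(all(sizes >= 1))
})

test_that("library molecules carry the well's barcode structure", {
  scheme <- default_scheme()
  allele <- random_dna(200)
  mol <- build_library_molecule(allele, "A01", scheme)
  expect_identical(substr(mol, 1, 11), "GATTATAGCCT")
  expect_identical(substr(mol, 12, 28), scheme$row_linker)
  # molecule length = allele + (3+8+17) + (3+8+24)
  expect_identical(nchar(mol), nchar(allele) + 28L + 35L)
  expect_identical(substring(mol, nchar(mol) - 34),
                   revcomp(paste0("GATATTACTCG", scheme$column_linker)))
  expect_error(build_library_molecule(allele, "Z99", scheme), "unknown well")
})

test_that("read emission is strand-balanced and substring-exact at zero error", {
  scheme <- default_scheme()
  mol <- build_library_molecule(random_dna(180), "C05", scheme)
  set.seed(151)
  reads <- simulate_reads(mol, 10000L, read_length = 120L, error_rate = 0)
  plus <- startsWith(reads$seq1, substr(mol, 1, 30))
  minus <- startsWith(reads$seq1, substr(revcomp(mol), 1, 30))
  expect_true(all(plus | minus))
  expect_identical(reads$seq1[plus][1], substr(mol, 1, 120))
  expect_identical(reads$seq2[plus][1],
                   revcomp(substring(mol, nchar(mol) - 119)))
  # binomial 3-sigma band around half
  p <- mean(plus)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("substitution errors occur at the configured binomial rate", {
  mol <- random_dna(200)
  set.seed(161)
  reads <- simulate_reads(mol, 500L, read_length = 200L, error_rate = 0.01)
  # force plus-strand comparison by matching each read to its template
  mm <- vapply(seq_len(500), function(i) {
    tpl <- if (startsWith(reads$seq1[i], substr(mol, 1, 20)) ||
               oracle_hamming(substr(reads$seq1[i], 1, 20),
                              substr(mol, 1, 20)) < 5) mol else revcomp(mol)
    oracle_hamming(reads$seq1[i], tpl)
  }, integer(1))
  n_bases <- 500 * 200
  expected <- n_bases * 0.01
  expect_lt(abs(sum(mm) - expected), 3 * sqrt(n_bases * 0.01 * 0.99))
  # errored bases get the low quality character
  i <- which(mm > 0)[1]
  expect_identical(lengths(regmatches(reads$qual1[i],
                                      gregexpr("\\+", reads$qual1[i]))),
                   1L * mm[i])
})

test_that("plate simulation is seed-deterministic with full truth coverage", {
  cfg <- sim_config(seed = 19, substitution_error_rate = 0.001)
  a <- simulate_plate(cfg)
  b <- simulate_plate(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_identical(nrow(a$truth), 96L)
  expect_setequal(a$truth$well, default_scheme()$wells$label)
  # every emitted read is attributable to exactly one truth record
  read_wells <- sub("^sim_([A-H][0-9]+)_.*$", "\\1", a$reads$id)
  expect_true(all(read_wells %in% a$truth$well))
  by_well <- table(factor(read_wells, levels = a$truth$well))
  expect_identical(as.integer(by_well[a$truth$well]), a$truth$n_reads)
})

test_that("an all-empty plate emits no reads but keeps 96 truth records", {
  cfg <- sim_config(seed = 23, empty_well_probability = 1)
  sim <- simulate_plate(cfg)
  expect_identical(nrow(sim$reads), 0L)
  expect_identical(nrow(sim$truth), 96L)
  expect_true(all(sim$truth$n_reads == 0L))
})

test_that("written fixtures round-trip through the readers", {
  scheme <- default_scheme()
  cfg <- sim_config(seed = 29, substitution_error_rate = 0,
                    wells = scheme$wells$label[1:4],
                    low_read_probability = 0, empty_well_probability = 0)
  sim <- simulate_plate(cfg, scheme, reads_per_well = 15L)
  d <- tempfile()
  paths <- write_simulated_plate(sim, d)
  back <- read_fastq_pair(paths$fastq1, paths$fastq2)
  expect_identical(back$seq1, sim$reads$seq1)
  expect_identical(back$qual2, sim$reads$qual2)
  expect_identical(back$id, sim$reads$id)
  # path-list loader finds the same pairs
  via_list <- read_fastq_pairs(paths$fastq_paths)
  expect_identical(via_list$seq1, sim$reads$seq1)
  # scheme and locus reload from the metadata files
  scheme2 <- load_scheme(paths$fwd_primers, paths$rev_primers)
  expect_identical(scheme2$primers, scheme$primers)
  locus2 <- read_target_bed(paths$bed, paths$reference,
                            read_donor_diffs(paths$donor))
  expect_identical(locus2$reference_amplicon,
                   cfg$locus$reference_amplicon)
  expect_identical(locus2$roi$label, cfg$locus$roi$label)
  expect_identical(locus2$donor_diffs, cfg$locus$donor_diffs)
})
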