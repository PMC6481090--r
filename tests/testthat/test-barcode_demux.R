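test_that("shipped primer files decompose into spacer, barcodes and linkers", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  expect_identical(scheme$spacer, "GAT")
  expect_identical(scheme$barcode_length, 8L)
  expect_identical(scheme$row_linker, "GTAAAACGACGGCCAGT")
  expect_identical(scheme$column_linker, "AGCGGATAACAATTTCACACAGGA")
  expect_identical(nrow(scheme$wells), 96L)
  expect_false(anyDuplicated(scheme$wells$label) > 0)
  p <- scheme$primers
  expect_identical(p$barcode[p$id == "iR5_A"], "TATAGCCT")
  expect_identical(p$barcode[p$id == "iC701"], "ATTACTCG")
  # decomposition reassembles every oligo exactly
  expect_identical(paste0(p$spacer, p$barcode, p$linker), p$full_sequence)
})

test_that("toy scheme decomposition splits spacer, barcode, linker", {
  fwd <- tempfile(); rev <- tempfile()
  writeLines(c("f1 GATAAAACCCC", "f2 GATTTTTCCCC"), fwd)
  writeLines(c("r1 GATCCCCGGGG", "r2 GATAAAAGGGG"), rev)
  scheme <- load_scheme(fwd, rev)
  expect_identical(scheme$spacer, "GAT")
  expect_identical(scheme$row_linker, "CCCC")
  expect_identical(scheme$column_linker, "GGGG")
  p <- scheme$primers
  expect_setequal(p$barcode[p$group == "row"], c("AAAA", "TTTT"))
  expect_setequal(p$barcode[p$group == "column"], c("CCCC", "AAAA"))
})

test_that("randomly generated schemes round-trip through the loader", {
  set.seed(11)
  for (trial in 1:5) {
    make_bc <- function(n, first) {
      # vary first and last characters so no barcode base leaks into the
      # common prefix/suffix
      vapply(seq_len(n), function(i) {
        paste0(first[(i - 1) %% 4 + 1],
               random_dna(6),
               c("A", "C", "G", "T")[(i) %% 4 + 1])
      }, character(1))
    }
    repeat {
      row_bc <- make_bc(8, c("A", "C", "G", "T"))
      col_bc <- make_bc(12, c("T", "G", "C", "A"))
      if (!anyDuplicated(row_bc) && !anyDuplicated(col_bc)) break
    }
    row_link <- paste0("GTAA", random_dna(10))
    col_link <- paste0("AGCG", random_dna(12))
    fwd <- tempfile(); rev <- tempfile()
    writeLines(sprintf("F%02d\tGAT%s%s", seq_along(row_bc), row_bc, row_link),
               fwd)
    writeLines(sprintf("R%02d\tGAT%s%s", seq_along(col_bc), col_bc, col_link),
               rev)
    scheme <- load_scheme(fwd, rev)
    expect_identical(scheme$spacer, "GAT")
    expect_identical(scheme$row_linker, row_link)
    expect_identical(scheme$column_linker, col_link)
    expect_identical(scheme$primers$barcode[scheme$primers$group == "row"],
                     row_bc)
    expect_identical(scheme$primers$barcode[scheme$primers$group == "column"],
                     col_bc)
  }
})

test_that("malformed primer files are rejected", {
  f <- tempfile()
  writeLines(c("f1 GATAAAACCCC", "f2 GATTTXTCCCC"), f)
  expect_error(load_scheme(f, table1_rev()), "non-ACGT")
  writeLines("f1 GATAAAACCCC", f)
  expect_error(load_scheme(f, table1_rev()), "at least two")
  writeLines(c("{\\rtf1 junk", "more"), f)
  expect_error(load_scheme(f, table1_rev()), "rich text")
  writeLines(c("f1 GATAAAACCCC", "f2 GATAAAACCCC", "f3 GATTTTTCCCC"), f)
  rev4 <- tempfile()
  writeLines(c("r1 GATCCCCGGGG", "r2 GATAAAAGGGG"), rev4)
  expect_error(load_scheme(f, rev4), "duplicate barcode")
})

test_that("assign_barcode matches exact prefixes and rejects N runs", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  res <- assign_barcode(paste0("GATTATAGCCTGTAAAACGACGGCCAGT", "ACGT"),
                        "row", scheme)
  expect_identical(res$id, "iR5_A")
  expect_identical(res$mismatches, 0L)
  res_n <- assign_barcode(strrep("N", 40), "row", scheme)
  expect_true(is.na(res_n$id))
})

test_that("single-base barcode mutations never reassign a well", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  for (group in c("row", "column")) {
    g <- scheme$primers[scheme$primers$group == group, ]
    linker <- g$linker[1]
    recovered <- 0L; total <- 0L
    for (k in seq_len(nrow(g))) {
      bc <- g$barcode[k]
      for (pos in 1:8) {
        for (alt in setdiff(c("A", "C", "G", "T"),
                            substr(bc, pos, pos))) {
          mut <- bc
          substr(mut, pos, pos) <- alt
          res <- assign_barcode(paste0("GAT", mut, linker), group, scheme,
                                max_mismatch = 1L)
          # oracle: exhaustive distances over the whole group
          d <- vapply(g$barcode, function(b) oracle_hamming(b, mut),
                      integer(1))
          qualifying <- which(d <= 1)
          total <- total + 1L
          if (length(qualifying) == 1L) {
            expect_identical(res$id, g$id[k])
            recovered <- recovered + 1L
          } else {
            # ambiguity may only ever drop the read, never move it
            expect_true(is.na(res$id))
            expect_identical(res$reason, "ambiguous_barcode")
          }
        }
      }
    }
    expect_gt(recovered / total, 0.9)
  }
})

test_that("pair demultiplexing works in both orientations and trims", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  allele <- random_dna(150)
  pr <- exact_pair_for_well(scheme, "A01", allele)
  fwd <- demultiplex_pair(pr$seq1, pr$seq2, scheme)
  expect_identical(fwd$well, "A01")
  expect_identical(fwd$orientation, "row_first")
  expect_identical(fwd$mismatches, 0L)
  swp <- demultiplex_pair(pr$seq2, pr$seq1, scheme)
  expect_identical(swp$well, "A01")
  expect_identical(swp$orientation, "column_first")
  # trimming removes the full spacer+barcode+linker and reorients to the
  # plate frame: trimmed mate 1 is always the row-side read
  expect_identical(fwd$trim_seq1, substring(pr$seq1, 28 + 1))
  expect_identical(fwd$trim_seq2, substring(pr$seq2, 35 + 1))
  expect_identical(swp$trim_seq1, substring(pr$seq1, 28 + 1))
  expect_identical(swp$trim_seq2, substring(pr$seq2, 35 + 1))
})

test_that("all 96 exact barcode combinations map to 96 distinct wells", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  allele <- random_dna(120)
  pairs <- do.call(rbind, lapply(scheme$wells$label, function(lb) {
    pr <- exact_pair_for_well(scheme, lb, allele)
    data.frame(id = lb, seq1 = pr$seq1, qual1 = strrep("I", nchar(pr$seq1)),
               seq2 = pr$seq2, qual2 = strrep("I", nchar(pr$seq2)),
               stringsAsFactors = FALSE)
  }))
  asg <- demultiplex_pairs(pairs, scheme)
  expect_identical(asg$well, asg$id)  # oracle: constructing well label
  expect_identical(sum(is.na(asg$well)), 0L)
})

test_that("reads without barcode structure stay unassigned", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  set.seed(99)
  pairs <- data.frame(id = sprintf("r%d", 1:1000),
                      seq1 = vapply(1:1000, function(i) random_dna(250),
                                    character(1)),
                      seq2 = vapply(1:1000, function(i) random_dna(250),
                                    character(1)),
                      stringsAsFactors = FALSE)
  pairs$qual1 <- strrep("I", 250)
  pairs$qual2 <- strrep("I", 250)
  asg <- demultiplex_pairs(pairs, scheme)
  expect_lte(sum(!is.na(asg$well)), 1L)
})

test_that("demultiplex_run conserves counts and handles empty input", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, "R1.fastq"); f2 <- file.path(d, "R2.fastq")
  file.create(f1, f2)
  res <- demultiplex_run(f1, f2, scheme)
  expect_identical(sum(res$counts$assigned), 0L)
  expect_identical(res$unassigned, 0L)

  cfg <- sim_config(seed = 3, substitution_error_rate = 0,
                    wells = scheme$wells$label[1:12],
                    low_read_probability = 0, empty_well_probability = 0)
  sim <- simulate_plate(cfg, scheme, reads_per_well = 30L)
  write_fastq(sim$reads$id, sim$reads$seq1, sim$reads$qual1, f1)
  write_fastq(sim$reads$id, sim$reads$seq2, sim$reads$qual2, f2)
  res <- demultiplex_run(f1, f2, scheme)
  expect_identical(sum(res$counts$assigned) + res$unassigned,
                   nrow(sim$reads))
  # at zero error rate every read lands in its generating well
  truth_well <- sub("^sim_([A-H][0-9]+)_.*$", "\\1",
                    res$assignments$id)
  expect_identical(res$assignments$well, truth_well)
})

test_that("demultiplexing is deterministic", {
  scheme <- load_scheme(table1_fwd(), table1_rev())
  set.seed(5)
  pairs <- data.frame(id = sprintf("r%d", 1:50),
                      seq1 = vapply(1:50, function(i) random_dna(100),
                                    character(1)),
                      seq2 = vapply(1:50, function(i) random_dna(100),
                                    character(1)),
                      qual1 = strrep("I", 100), qual2 = strrep("I", 100),
                      stringsAsFactors = FALSE)
  expect_identical(demultiplex_pairs(pairs, scheme),
                   demultiplex_pairs(pairs, scheme))
})
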