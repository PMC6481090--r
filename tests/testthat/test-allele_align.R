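test_that("identity query aligns all-match with score match x length", {
  s <- random_dna(30)
  a <- align_semiglobal(s, s)
  expect_identical(a$ops$op, "match")
  expect_identical(a$ops$length, 30L)
  expect_equal(a$score, 30)
  expect_identical(a$ref_start, 0L)
  expect_identical(a$ref_end, 30L)
})

test_that("a single deletion is recovered and left-aligned", {
  a <- align_semiglobal("ACGACGT", "ACGTACGT")
  expect_equal(a$score, 7 - 5)
  expect_identical(a$ops$op, c("match", "deletion", "match"))
  expect_identical(a$ops$length, c(3L, 1L, 4L))
  v <- extract_variants(a, target_locus("t", "ACGTACGT"))
  expect_identical(v$kind, "deletion")
  expect_identical(v$pos, 3L)
  expect_identical(v$ref, "T")
})

test_that("a single substitution is reported at its offset", {
  ref <- random_dna(50)
  q <- ref
  substr(q, 23, 23) <- setdiff(c("A", "C", "G", "T"),
                               substr(ref, 23, 23))[1]
  a <- align_semiglobal(q, ref)
  v <- extract_variants(a, target_locus("t", ref))
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "substitution")
  expect_identical(v$pos, 22L)
  expect_identical(v$ref, substr(ref, 23, 23))
  expect_identical(v$alt, substr(q, 23, 23))
})

test_that("truncated fragments pay no end-gap penalty", {
  ref <- random_dna(60)
  q <- substr(ref, 11, 45)
  a <- align_semiglobal(q, ref)
  expect_equal(a$score, 35)
  expect_identical(a$ref_start, 10L)
  expect_identical(a$ref_end, 45L)
  expect_identical(nrow(extract_variants(a, target_locus("t", ref))), 0L)
})

test_that("alignment scores equal an independent full DP on random instances", {
  set.seed(81)
  for (i in 1:300) {
    q <- random_dna(sample(1:12, 1))
    r <- random_dna(sample(1:12, 1))
    expect_equal(align_semiglobal(q, r)$score, oracle_align_score(q, r),
                 info = paste(q, r))
  }
})

test_that("indels in homopolymers are left-aligned, and re-alignment is idempotent", {
  ref <- paste0("GGCC", "AAAA", "TTCGG")   # homopolymer A at 4..7
  # delete one A: every placement is equivalent; leftmost must be reported
  q <- paste0("GGCC", "AAA", "TTCGG")
  v <- extract_variants(align_semiglobal(q, ref), target_locus("t", ref))
  expect_identical(v$kind, "deletion")
  # oracle: minimum over all equivalent single-base deletion placements
  ps <- seq_len(nchar(ref))
  equivalent <- vapply(ps, function(p) {
    paste0(substr(ref, 1, p - 1), substring(ref, p + 1)) == q
  }, logical(1))
  expect_identical(v$pos, as.integer(min(ps[equivalent]) - 1L))
  # idempotence: left-aligning the already left-aligned indel changes nothing
  la <- ampliwell:::left_align_indel(v$pos, v$ref, ref)
  expect_identical(la$pos, v$pos)
  expect_identical(la$allele, v$ref)
  # insertion into the homopolymer likewise left-aligns
  qi <- paste0("GGCC", "AAAAA", "TTCGG")
  vi <- extract_variants(align_semiglobal(qi, ref), target_locus("t", ref))
  expect_identical(vi$kind, "insertion")
  expect_identical(vi$pos, 4L)  # anchored before the first A of the run
  expect_identical(vi$alt, "A")
})

test_that("a deletion spanning the gRNA region is tagged with its label", {
  locus <- toy_locus()
  ref <- locus$reference_amplicon
  q <- paste0(substr(ref, 1, 28), substring(ref, 32))  # delete 29..31
  v <- extract_variants(align_semiglobal(q, ref), locus)
  expect_identical(v$kind, "deletion")
  expect_match(v$roi, "gRNA")
})

test_that("allele classification covers the whole rule table", {
  locus <- toy_locus()
  donor <- locus$donor_diffs
  sub_v <- function(pos, ref, alt) {
    data.frame(pos = pos, kind = "substitution", ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  del_v <- data.frame(pos = 10L, kind = "deletion", ref = "T", alt = "",
                      stringsAsFactors = FALSE)
  donor_v <- sub_v(donor$pos, donor$ref, donor$alt)
  other_v <- sub_v(5L, substr(locus$reference_amplicon, 6, 6), "T")
  none <- donor_v[0, ]
  expect_identical(classify_allele(none, locus), "WT")
  expect_identical(classify_allele(donor_v, locus), "HDR")
  expect_identical(classify_allele(other_v, locus), "substitution_only")
  expect_identical(classify_allele(del_v, locus), "NHEJ_indel")
  expect_identical(classify_allele(rbind(donor_v, other_v), locus), "complex")
  expect_identical(classify_allele(rbind(donor_v, del_v), locus), "complex")
  expect_identical(classify_allele(rbind(other_v, del_v), locus),
                   "NHEJ_indel")
  expect_identical(classify_allele(rbind(donor_v, other_v, del_v), locus),
                   "complex")
  # without a donor specification the HDR/complex branches vanish
  plain <- toy_locus(donor = FALSE)
  expect_identical(classify_allele(donor_v, plain), "substitution_only")
  expect_identical(classify_allele(rbind(donor_v, del_v), plain),
                   "NHEJ_indel")
})

test_that("classification is total over generated variant lists", {
  locus <- toy_locus()
  set.seed(91)
  kinds <- c("substitution", "insertion", "deletion")
  for (i in 1:100) {
    n <- sample(0:4, 1)
    v <- data.frame(pos = sample(0:55, max(n, 1)),
                    kind = sample(kinds, max(n, 1), replace = TRUE),
                    ref = "A", alt = "T",
                    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
    cls <- classify_allele(v, locus)
    expect_true(cls %in% c("WT", "HDR", "NHEJ_indel", "substitution_only",
                           "complex"))
  }
})

test_that("amplicon design checks flag bad geometry and missing het SNP", {
  expect_length(validate_amplicon_design(0, 350, 175, 350,
                                         has_het_snp = TRUE), 0L)
  w <- validate_amplicon_design(0, 450, 225, 450, has_het_snp = TRUE)
  expect_true(any(grepl("150-200", w)))
  expect_true(any(grepl("300-400", w)))
  w2 <- validate_amplicon_design(175, 350, 175, 350, has_het_snp = TRUE)
  expect_true(any(grepl("150-200", w2)))
  w3 <- validate_amplicon_design(0, 350, 175, 350)
  expect_true(any(grepl("homozygote", w3)))
})
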