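# Independent oracles and small fixture builders. These deliberately share
# no code with the package internals they are used to check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

str_chars <- function(s) strsplit(s, "")[[1]]

# Plain-R affine-gap semi-global DP, score only: query aligned end to end,
# unaligned reference overhangs free; a gap of length k costs
# open + (k-1) * extend.
oracle_align_score <- function(q, r, sc = list(match = 1, mismatch = -2,
                                               gap_open = -5,
                                               gap_extend = -1)) {
  qc <- str_chars(q); rc <- str_chars(r)
  n <- length(qc); m <- length(rc)
  NEG <- -Inf
  H <- matrix(NEG, n + 1, m + 1)  # diagonal state
  E <- matrix(NEG, n + 1, m + 1)  # gap in reference (query base aligned to -)
  F <- matrix(NEG, n + 1, m + 1)  # gap in query (reference base aligned to -)
  H[1, ] <- 0
  for (i in seq_len(n)) {
    E[i + 1, 1] <- sc$gap_open + (i - 1) * sc$gap_extend
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qc[i] == rc[j] && qc[i] != "N") sc$match else sc$mismatch
      H[i + 1, j + 1] <- max(H[i, j], E[i, j], F[i, j]) + s
      E[i + 1, j + 1] <- max(H[i, j + 1] + sc$gap_open,
                             F[i, j + 1] + sc$gap_open,
                             E[i, j + 1] + sc$gap_extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] + sc$gap_open,
                             E[i + 1, j] + sc$gap_open,
                             F[i + 1, j] + sc$gap_extend)
    }
  }
  max(H[n + 1, ], E[n + 1, ])
}

# Exhaustive overlap scan: every suffix(seq1)/prefix(seq2rc) offset,
# minimal mismatch ratio, ties to the longer overlap.
oracle_best_overlap <- function(s1, s2rc, min_overlap,
                                max_mismatch_ratio = 0.25) {
  c1 <- str_chars(s1); c2 <- str_chars(s2rc)
  best <- NULL
  for (ov in seq(min_overlap, min(length(c1), length(c2)))) {
    a <- c1[(length(c1) - ov + 1):length(c1)]
    b <- c2[1:ov]
    mm <- sum(a != b)
    ratio <- mm / ov
    if (is.null(best) || ratio < best$ratio - 1e-12 ||
        (abs(ratio - best$ratio) <= 1e-12 && ov > best$overlap)) {
      best <- list(overlap = ov, mismatches = mm, ratio = ratio)
    }
  }
  if (is.null(best) || best$ratio > max_mismatch_ratio + 1e-12) return(NULL)
  best[c("overlap", "mismatches")]
}

# Hamming distance between equal-length strings
oracle_hamming <- function(a, b) sum(str_chars(a) != str_chars(b))

table1_fwd <- function() system.file("extdata", "barcode_primers_fwd.txt",
                                     package = "ampliwell")
table1_rev <- function() system.file("extdata", "barcode_primers_rev.txt",
                                     package = "ampliwell")

# small locus: 60 bp amplicon, cut at 30, donor substitution at the cut
toy_locus <- function(donor = TRUE) {
  ref <- paste0("ATGCGTACGTTAGCCATGGCAACGTTGCAC",
                "GTTAACGGATCCATGCAAGCTTGGCACTGA")
  dd <- if (donor) {
    data.frame(pos = 30L, ref = substr(ref, 31, 31), alt = "T",
               stringsAsFactors = FALSE)
  }
  target_locus("toy", ref, chrom = "chrT", start = 100L,
               roi = data.frame(label = "gRNA", start = 20L, end = 40L,
                                stringsAsFactors = FALSE),
               donor_diffs = dd)
}

# exact-prefix read pair for a given well, error free
exact_pair_for_well <- function(scheme, label, allele,
                                read_length = 120L) {
  w <- scheme$wells[scheme$wells$label == label, ]
  p <- scheme$primers
  rowp <- p$full_sequence[p$id == w$row_id]
  colp <- p$full_sequence[p$id == w$column_id]
  mol <- paste0(rowp, allele, revcomp(colp))
  L <- min(read_length, nchar(mol))
  list(seq1 = substr(mol, 1, L),
       seq2 = revcomp(substring(mol, nchar(mol) - L + 1)))
}
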