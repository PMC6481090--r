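# Overlap merging ("flashing"): amplicons are short enough (~300-400 bp)
# that 2 x 250 bp mates overlap in the middle, so the original fragment can
# be reconstructed from one pair. Only substitutions are considered inside
# the overlap; indels between mates of a single molecule do not occur.

#' Best suffix/prefix overlap between a read and its mate
#'
#' Scans every overlap length from `min_overlap` up to the shorter
#' sequence, comparing the suffix of `seq1` with the prefix of
#' `seq2_revcomp`, and returns the overlap with the minimal mismatch
#' ratio (ties go to the longer overlap).
#'
#' @param seq1 forward-mate sequence (5'->3').
#' @param seq2_revcomp reverse mate already reverse-complemented into the
#'   forward frame.
#' @param min_overlap smallest overlap length considered.
#' @param max_mismatch_ratio maximum tolerated mismatches/overlap.
#' @return list with `overlap` and `mismatches`, or `NULL` when no
#'   qualifying overlap exists.
#' @export
find_best_overlap <- function(seq1, seq2_revcomp, min_overlap = 10L,
                              max_mismatch_ratio = 0.25) {
  stopifnot(nzchar(seq1), nzchar(seq2_revcomp))
  res <- best_overlap_cpp(seq1, seq2_revcomp, as.integer(min_overlap),
                          max_mismatch_ratio)
  if (res[1] < 0L) return(NULL)
  list(overlap = res[1], mismatches = res[2])
}

#' Merge trimmed read pairs into amplicon fragments
#'
#' Reverse-complements each second mate, finds the best overlap
#' ([find_best_overlap()]), and emits the consensus fragment. Within the
#' overlap the base with the higher Phred quality wins (ties keep mate 1's
#' base) and the consensus quality is the maximum of the two.
#'
#' @param seq1,qual1,seq2,qual2 equal-length character vectors of trimmed
#'   mate sequences and Phred+33 quality strings (`seq2`/`qual2` in raw
#'   reverse-strand orientation, as sequenced).
#' @param min_overlap,max_mismatch_ratio see [find_best_overlap()].
#' @return data frame with `sequence`, `quality`, `overlap`, `mismatches`,
#'   `merged` (logical) and `reason` (`"none"` or `"no_overlap"`); failed
#'   rows carry `NA` sequences.
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                        max_mismatch_ratio = 0.25) {
  stopifnot(length(seq1) == length(seq2),
            all(nchar(seq1) == nchar(qual1)),
            all(nchar(seq2) == nchar(qual2)))
  if (!length(seq1)) {
    return(data.frame(sequence = character(), quality = character(),
                      overlap = integer(), mismatches = integer(),
                      merged = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  res <- merge_pairs_cpp(seq1, qual1, seq2, qual2,
                         as.integer(min_overlap), max_mismatch_ratio)
  merged <- !is.na(res$sequence)
  data.frame(sequence = res$sequence, quality = res$quality,
             overlap = res$overlap, mismatches = res$mismatches,
             merged = merged,
             reason = ifelse(merged, "none", "no_overlap"),
             stringsAsFactors = FALSE)
}

#' Merge one read pair
#'
#' @inheritParams merge_pairs
#' @return one-row data frame; see [merge_pairs()].
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                       max_mismatch_ratio = 0.25) {
  merge_pairs(seq1, qual1, seq2, qual2, min_overlap, max_mismatch_ratio)
}

#' Merge the assigned pairs of a demultiplexed run
#'
#' @param assignments output of [demultiplex_pairs()].
#' @param min_overlap,max_mismatch_ratio see [find_best_overlap()].
#' @return data frame of assigned pairs with merge columns appended
#'   (`well` retained), one row per assigned pair.
#' @export
merge_assigned <- function(assignments, min_overlap = 10L,
                           max_mismatch_ratio = 0.25) {
  asg <- assignments[!is.na(assignments$well), , drop = FALSE]
  m <- merge_pairs(asg$trim_seq1, asg$trim_qual1, asg$trim_seq2,
                   asg$trim_qual2, min_overlap, max_mismatch_ratio)
  cbind(asg[, c("id", "well"), drop = FALSE], m)
}
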