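# Per-well allele counting and genotype calling. Each unique merged
# fragment sequence is one observed allele; a well is only reported when it
# reaches the read threshold, and at most `ploidy` alleles above the noise
# fraction are called.

#' Collapse merged fragments into unique alleles with counts
#'
#' Groups identical fragment sequences, counts them, and (when a locus is
#' given) aligns each unique allele to the reference amplicon -- in both
#' orientations, keeping the higher-scoring one -- to extract its variants
#' and class.
#'
#' @param sequences character vector of merged fragment sequences from one
#'   well.
#' @param locus optional [target_locus()]; enables variant extraction and
#'   classification.
#' @param scoring alignment scoring, see [default_scoring()].
#' @return data frame sorted by decreasing count (ties broken
#'   lexicographically by sequence) with `sequence`, `count`, `fraction`,
#'   and -- when `locus` is given -- `allele_class`, `n_variants`,
#'   `variant_notation`, plus a list column `variants`.
#' @export
collapse_alleles <- function(sequences, locus = NULL,
                             scoring = default_scoring()) {
  sequences <- sequences[!is.na(sequences)]
  if (!length(sequences)) {
    out <- data.frame(sequence = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    if (!is.null(locus)) {
      out$allele_class <- character()
      out$n_variants <- integer()
      out$variant_notation <- character()
      out$variants <- list()
    }
    return(out)
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out$fraction <- out$count / sum(out$count)
  if (!is.null(locus)) {
    ann <- annotate_alleles(out$sequence, locus, scoring)
    out$allele_class <- ann$allele_class
    out$n_variants <- ann$n_variants
    out$variant_notation <- ann$variant_notation
    out$variants <- ann$variants
  }
  out
}

#' Align and classify unique allele sequences
#'
#' @param sequences unique allele sequences.
#' @param locus a [target_locus()].
#' @param scoring alignment scoring.
#' @return data frame with `allele_class`, `n_variants`,
#'   `variant_notation` and a `variants` list column (one
#'   [extract_variants()] frame per allele).
#' @export
annotate_alleles <- function(sequences, locus,
                             scoring = default_scoring()) {
  ref <- locus$reference_amplicon
  variants <- vector("list", length(sequences))
  cls <- character(length(sequences))
  for (i in seq_along(sequences)) {
    aln <- align_semiglobal(sequences[i], ref, scoring)
    # guard against swapped primer files / strand flips: only worth
    # checking when the forward-strand alignment is poor
    if (aln$score < 0.5 * scoring$match * nchar(sequences[i])) {
      aln_rc <- align_semiglobal(revcomp(sequences[i]), ref, scoring)
      if (aln_rc$score > aln$score) aln <- aln_rc
    }
    v <- extract_variants(aln, locus)
    variants[[i]] <- v
    cls[i] <- classify_allele(v, locus)
  }
  data.frame(allele_class = cls,
             n_variants = vapply(variants, nrow, integer(1)),
             variant_notation = vapply(variants, variant_notation,
                                       character(1)),
             variants = I(variants), stringsAsFactors = FALSE)
}

#' Call a well genotype from its allele counts
#'
#' Wells under the read threshold fail (`failed_low_reads`); otherwise
#' alleles with at least `min_allele_fraction` of the well's reads are
#' kept and the top `ploidy` by count are called. A single surviving
#' allele is reported `ploidy` times with `homozygote_flag` set -- a flag,
#' not a certainty, since a large deletion removing one primer site
#' produces the same signal.
#'
#' @param alleles a [collapse_alleles()] frame (with classes).
#' @param ploidy expected allele count per cell (>= 1).
#' @param min_reads read threshold below which the well fails.
#' @param min_allele_fraction noise floor on the allele fraction.
#' @param well well label.
#' @param n_input_reads read pairs assigned to the well before merging;
#'   a well with no input at all has status `empty`.
#' @return one-row data frame: `well`, `status` (`reported` /
#'   `failed_low_reads` / `empty`), `total_merged_reads`,
#'   `genotype_string`, `homozygote_flag`, `n_called`, plus a
#'   `called_alleles` list column holding the called subset of `alleles`.
#' @export
call_genotype <- function(alleles, ploidy = 2L, min_reads = 10L,
                          min_allele_fraction = 0.15, well = NA_character_,
                          n_input_reads = NULL) {
  if (ploidy < 1L) stop("ploidy must be >= 1")
  total <- if (nrow(alleles)) sum(alleles$count) else 0L
  if (is.null(n_input_reads)) n_input_reads <- total
  empty_called <- alleles[0, , drop = FALSE]
  if (n_input_reads == 0L && total == 0L) {
    status <- "empty"; gt <- NA_character_; hom <- NA; called <- empty_called
  } else if (total < min_reads) {
    status <- "failed_low_reads"; gt <- NA_character_; hom <- NA
    called <- empty_called
  } else {
    keep <- alleles[alleles$fraction >= min_allele_fraction, , drop = FALSE]
    called <- keep[seq_len(min(nrow(keep), ploidy)), , drop = FALSE]
    status <- "reported"
    if (nrow(called) == 1L) {
      gt <- paste(rep(called$allele_class, ploidy), collapse = "/")
      hom <- TRUE
    } else {
      gt <- paste(called$allele_class, collapse = "/")
      hom <- FALSE
    }
  }
  data.frame(well = well, status = status,
             total_merged_reads = as.integer(total),
             n_input_reads = as.integer(n_input_reads),
             genotype_string = gt, homozygote_flag = hom,
             n_called = nrow(called),
             called_alleles = I(list(called)), stringsAsFactors = FALSE)
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarise plate-level screening success
#'
#' @param wells data frame of per-well calls ([call_genotype()] rows).
#' @return data frame with `wells_processed` (wells with any input reads),
#'   `wells_sequenced` (status `reported`), and `success_rate`
#'   (percentage, one decimal, half away from zero).
#' @export
summarize_plate <- function(wells) {
  processed <- sum(wells$status != "empty")
  if (processed == 0L) stop("no processed wells: success rate undefined")
  sequenced <- sum(wells$status == "reported")
  data.frame(wells_processed = processed, wells_sequenced = sequenced,
             success_rate = round_half_up(100 * sequenced / processed, 1))
}
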