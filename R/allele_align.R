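# Alignment of merged fragments to the reference amplicon, variant
# extraction with indel left-alignment, and allele classification relative
# to the programmed edit.

#' Default alignment scoring
#'
#' match +1, mismatch -2, gap_open -5, gap_extend -1; a gap of length k
#' costs `gap_open + (k-1) * gap_extend`, so a 1 bp indel (5) is cheaper
#' than two substitutions (6) -- the right prior for Cas9 cut-site repair.
#'
#' @return named list of scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -1)
}

#' Semi-global affine-gap alignment of a fragment to the amplicon
#'
#' The query (fragment) must align end to end; unaligned reference on
#' either side is free, so truncated fragments are not penalised for the
#' amplicon they do not cover. Traceback is deterministic: ties prefer
#' diagonal moves, then deletions, then insertions.
#'
#' @param query fragment sequence.
#' @param reference amplicon sequence.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (see [default_scoring()]).
#' When the query has the reference's length and at most one mismatching
#' position, the gap-free diagonal alignment is provably optimal (a single
#' substitution costs 3 while any gap costs at least 5, and any shifted or
#' gapped path forfeits more), so it is returned without running the DP.
#'
#' @return object of class `semiglobal_alignment`: list with `score`,
#'   `ops` (data frame of run-length encoded operations with `op` in
#'   match/mismatch/insertion/deletion and `length`), `ref_start`,
#'   `ref_end` (0-based half-open reference span), `query`, `reference`.
#' @export
align_semiglobal <- function(query, reference, scoring = default_scoring()) {
  stopifnot(nzchar(query), nzchar(reference))
  if (nchar(query) == nchar(reference)) {
    mm <- hamming_matrix_cpp(query, reference)[1, 1]
    min_gap_loss <- scoring$match - scoring$gap_open
    sub_loss <- scoring$match - scoring$mismatch
    if (!is.na(mm) && mm * sub_loss < min_gap_loss &&
        !grepl("N", query, fixed = TRUE)) {
      d <- which(charToRaw(query) != charToRaw(reference))
      kind <- rep("match", nchar(query)); kind[d] <- "mismatch"
      r <- rle(kind)
      return(structure(list(
        score = scoring$match * (nchar(query) - mm) + scoring$mismatch * mm,
        ops = data.frame(op = r$values, length = r$lengths,
                         stringsAsFactors = FALSE),
        ref_start = 0L, ref_end = nchar(reference), query = query,
        reference = reference), class = "semiglobal_alignment"))
    }
  }
  res <- align_semiglobal_cpp(query, reference, scoring$match,
                              scoring$mismatch, scoring$gap_open,
                              scoring$gap_extend)
  r <- rle(strsplit(res$ops, "")[[1]])
  ops <- data.frame(op = c("=" = "match", "X" = "mismatch",
                           "I" = "insertion", "D" = "deletion")[r$values],
                    length = r$lengths, stringsAsFactors = FALSE)
  rownames(ops) <- NULL
  structure(list(score = res$score, ops = ops, ref_start = res$ref_start,
                 ref_end = res$ref_end, query = query,
                 reference = reference),
            class = "semiglobal_alignment")
}

#' @export
print.semiglobal_alignment <- function(x, ...) {
  cigar <- paste0(x$ops$length,
                  c(match = "=", mismatch = "X", insertion = "I",
                    deletion = "D")[x$ops$op], collapse = "")
  cat("semiglobal_alignment: score", x$score, "ref", x$ref_start, "-",
      x$ref_end, "cigar", cigar, "\n")
  invisible(x)
}

left_align_indel <- function(pos, allele, reference) {
  # shift an indel left while the base preceding it equals its last base;
  # `allele` is the inserted or deleted sequence
  n <- nchar(allele)
  while (pos > 0L &&
         substr(reference, pos, pos) == substr(allele, n, n)) {
    allele <- paste0(substr(reference, pos, pos),
                     substr(allele, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

annotate_roi <- function(variants, locus) {
  if (!nrow(variants)) { variants$roi <- character(0); return(variants) }
  roi <- locus$roi
  variants$roi <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    span_start <- v$pos
    span_end <- if (v$kind == "deletion") v$pos + nchar(v$ref) else v$pos + 1L
    if (v$kind == "insertion") span_end <- v$pos  # point event
    hit <- roi$label[roi$start < max(span_end, span_start + 1L) &
                     roi$end > span_start]
    paste(hit, collapse = ",")
  }, character(1))
  variants
}

#' Extract variants from an alignment
#'
#' Adjacent gap columns of one type are reported as a single indel;
#' indels are left-aligned against the reference; each variant is
#' annotated with the regions of interest it touches.
#'
#' @param alignment an [align_semiglobal()] result.
#' @param locus a [target_locus()].
#' @return data frame with `pos` (0-based amplicon position; for an
#'   insertion, the reference position it precedes), `kind`
#'   (`substitution`/`insertion`/`deletion`), `ref`, `alt`, `roi`.
#' @export
extract_variants <- function(alignment, locus) {
  q <- alignment$query
  ref <- locus$reference_amplicon
  out <- list()
  qi <- 0L; ri <- alignment$ref_start
  for (k in seq_len(nrow(alignment$ops))) {
    op <- alignment$ops$op[k]; len <- alignment$ops$length[k]
    if (op == "match") {
      qi <- qi + len; ri <- ri + len
    } else if (op == "mismatch") {
      qs <- substr(q, qi + 1L, qi + len)
      rs <- substr(ref, ri + 1L, ri + len)
      for (p in seq_len(len)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = ri + p - 1L, kind = "substitution",
          ref = substr(rs, p, p), alt = substr(qs, p, p),
          stringsAsFactors = FALSE)
      }
      qi <- qi + len; ri <- ri + len
    } else if (op == "insertion") {
      ins <- substr(q, qi + 1L, qi + len)
      la <- left_align_indel(ri, ins, ref)
      out[[length(out) + 1L]] <- data.frame(
        pos = la$pos, kind = "insertion", ref = "", alt = la$allele,
        stringsAsFactors = FALSE)
      qi <- qi + len
    } else { # deletion
      del <- substr(ref, ri + 1L, ri + len)
      la <- left_align_indel(ri, del, ref)
      out[[length(out) + 1L]] <- data.frame(
        pos = la$pos, kind = "deletion", ref = la$allele, alt = "",
        stringsAsFactors = FALSE)
      ri <- ri + len
    }
  }
  variants <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(), kind = character(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  variants <- variants[order(variants$pos, variants$kind), , drop = FALSE]
  rownames(variants) <- NULL
  annotate_roi(variants, locus)
}

variant_notation <- function(variants) {
  if (!nrow(variants)) return("")
  paste(sprintf("%d:%s>%s", variants$pos,
                ifelse(variants$ref == "", "-", variants$ref),
                ifelse(variants$alt == "", "-", variants$alt)),
        collapse = ";")
}

ALLELE_CLASSES <- c("WT", "HDR", "NHEJ_indel", "substitution_only", "complex")

#' Classify an allele relative to the programmed edit
#'
#' Rules, applied in order: no variants is `WT`; variants exactly equal to
#' the donor substitutions is `HDR`; all donor substitutions present
#' together with anything else is `complex`; otherwise any indel is
#' `NHEJ_indel`; otherwise `substitution_only`.
#'
#' @param variants an [extract_variants()] data frame.
#' @param locus a [target_locus()]; its `donor_diffs` define the HDR
#'   allele (may be `NULL` when no HDR screen is intended).
#' @return one of `"WT"`, `"HDR"`, `"NHEJ_indel"`, `"substitution_only"`,
#'   `"complex"`.
#' @export
classify_allele <- function(variants, locus) {
  donor <- locus$donor_diffs
  if (!nrow(variants)) return("WT")
  has_indel <- any(variants$kind %in% c("insertion", "deletion"))
  if (!is.null(donor) && nrow(donor)) {
    vkey <- paste(variants$pos, variants$kind, variants$ref, variants$alt)
    dkey <- paste(donor$pos, "substitution", donor$ref, donor$alt)
    donor_all <- all(dkey %in% vkey)
    if (donor_all && nrow(variants) == nrow(donor)) return("HDR")
    if (donor_all) return("complex")
  }
  if (has_indel) return("NHEJ_indel")
  "substitution_only"
}

#' Check an amplicon design against screening guidelines
#'
#' Locus primers should sit 150-200 bp either side of the edit so that the
#' product is 300-400 bp, short enough for 2 x 250 bp mates to overlap.
#' Without a heterozygous SNP inside the product, a large deletion removing
#' one primer site can masquerade as a homozygote.
#'
#' @param primer_fwd_offset,primer_rev_offset 0-based amplicon offsets of
#'   the inner edge of each locus primer.
#' @param edit_position 0-based amplicon position of the edit site.
#' @param product_length amplicon length in bp.
#' @param has_het_snp whether a known heterozygous SNP lies inside the
#'   product (used to filter false homozygotes).
#' @return character vector of warnings (empty when the design is clean).
#' @export
validate_amplicon_design <- function(primer_fwd_offset, primer_rev_offset,
                                     edit_position, product_length,
                                     has_het_snp = FALSE) {
  warnings <- character()
  d_fwd <- edit_position - primer_fwd_offset
  d_rev <- primer_rev_offset - edit_position
  for (d in c(fwd = d_fwd, rev = d_rev)) {
    if (d < 150 || d > 200) {
      warnings <- c(warnings, sprintf(
        "primer-to-edit distance %d bp outside the recommended 150-200 bp", d))
    }
  }
  if (product_length < 300 || product_length > 400) {
    warnings <- c(warnings, sprintf(
      "product length %d bp outside the recommended 300-400 bp (must stay well under ~400 bp for mate overlap)",
      product_length))
  }
  if (!has_het_snp) {
    warnings <- c(warnings, paste(
      "no heterozygous SNP declared within the product:",
      "apparent homozygotes may be large-deletion artefacts removing one",
      "primer site; confirm with a >5 kb PCR"))
  }
  warnings
}
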