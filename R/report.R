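# Plate report rendering: a fixed-width text view of each allele against
# the reference amplicon (the manual-inspection view), plus machine
# readable TSVs. Output is deterministic: identical inputs give byte
# identical files.

build_alignment_rows <- function(sequence, locus,
                                 scoring = default_scoring()) {
  ref <- locus$reference_amplicon
  m <- nchar(ref)
  aln <- align_semiglobal(sequence, ref, scoring)
  rc <- revcomp(sequence)
  aln_rc <- align_semiglobal(rc, ref, scoring)
  if (aln_rc$score > aln$score) aln <- aln_rc
  variants <- extract_variants(aln, locus)

  ref_chars <- strsplit(ref, "")[[1]]
  allele <- ref_chars
  covered <- seq_len(m) > aln$ref_start & seq_len(m) <= aln$ref_end
  allele[!covered] <- "."
  insertions <- variants[variants$kind == "insertion", , drop = FALSE]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "substitution") {
      allele[v$pos + 1L] <- v$alt
    } else if (v$kind == "deletion") {
      allele[(v$pos + 1L):(v$pos + nchar(v$ref))] <- "-"
    }
  }
  match_row <- ifelse(!covered, " ",
                      ifelse(allele == ref_chars, "|", " "))
  ins_row <- rep(" ", m)
  ins_row[pmin(insertions$pos + 1L, m)] <- "^"
  roi_row <- rep(" ", m)
  for (i in seq_len(nrow(locus$roi))) {
    r <- locus$roi[i, ]
    roi_row[(r$start + 1L):r$end] <- "*"
  }
  list(roi = roi_row, ref = ref_chars, match = match_row, allele = allele,
       ins = ins_row, insertions = insertions, variants = variants,
       alignment = aln)
}

#' Render one allele against the reference amplicon as text
#'
#' Fixed-width blocks of four tracks per line: region-of-interest markers
#' (`*`), the reference, a match track (`|` match, space mismatch), and
#' the allele with deletions as `-` and uncovered reference as `.`.
#' Insertions are marked `^` at the anchored reference column and listed
#' as `+<pos>:<seq>` legend lines after the blocks, so the rendering is
#' lossless for any in-amplicon variant.
#'
#' @param sequence allele (merged fragment) sequence.
#' @param locus a [target_locus()].
#' @param width columns of reference per line.
#' @param scoring alignment scoring.
#' @return a single string (the text block).
#' @export
render_well_alignment <- function(sequence, locus, width = 60L,
                                  scoring = default_scoring()) {
  rows <- build_alignment_rows(sequence, locus, scoring)
  m <- length(rows$ref)
  lines <- character()
  for (from in seq(1L, m, by = width)) {
    to <- min(from + width - 1L, m)
    lines <- c(lines,
               sprintf("roi    %s", paste(rows$roi[from:to], collapse = "")),
               sprintf("%6d %s", from - 1L,
                       paste(rows$ref[from:to], collapse = "")),
               sprintf("       %s", paste(rows$match[from:to], collapse = "")),
               sprintf("allele %s", paste(rows$allele[from:to], collapse = "")),
               sprintf("ins    %s", paste(rows$ins[from:to], collapse = "")),
               "")
  }
  for (i in seq_len(nrow(rows$insertions))) {
    v <- rows$insertions[i, ]
    lines <- c(lines, sprintf("+%d:%s", v$pos, v$alt))
  }
  paste(lines, collapse = "\n")
}

# inverse of render_well_alignment, used to prove the rendering lossless
parse_alignment_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  ref <- paste(sub("^ *[0-9]+ ", "", grep("^ *[0-9]+ ", lines, value = TRUE)),
               collapse = "")
  allele <- paste(sub("^allele ", "", grep("^allele ", lines, value = TRUE)),
                  collapse = "")
  rc <- strsplit(ref, "")[[1]]
  ac <- strsplit(allele, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(rc)) {
    if (ac[i] == "-") {
      j <- i
      while (j < length(rc) && ac[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        pos = i - 1L, kind = "deletion",
        ref = paste(rc[i:j], collapse = ""), alt = "",
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      if (ac[i] != rc[i] && ac[i] != ".") {
        out[[length(out) + 1L]] <- data.frame(
          pos = i - 1L, kind = "substitution", ref = rc[i], alt = ac[i],
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  for (ln in grep("^\\+[0-9]+:", lines, value = TRUE)) {
    pos <- as.integer(sub("^\\+([0-9]+):.*$", "\\1", ln))
    alt <- sub("^\\+[0-9]+:", "", ln)
    out[[length(out) + 1L]] <- data.frame(
      pos = pos, kind = "insertion", ref = "", alt = alt,
      stringsAsFactors = FALSE)
  }
  v <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(), kind = character(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  v <- v[order(v$pos, v$kind), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Write a plate report to disk
#'
#' Always writes `wells.tsv`, `alleles.tsv`, `summary.tsv` and a
#' plain-text `report.txt`; optionally `report.html`. Files contain no
#' timestamps, so re-running on identical inputs reproduces them byte for
#' byte.
#'
#' @param report a `plate_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("tsv", "txt", "html")`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, formats = c("tsv", "txt")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wells_flat <- report$wells[, setdiff(names(report$wells),
                                       "called_alleles"), drop = FALSE]
  if ("tsv" %in% formats) {
    for (nm in c("wells", "alleles", "summary")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      obj <- switch(nm, wells = wells_flat, alleles = report$alleles,
                    summary = report$summary)
      write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (any(c("txt", "html") %in% formats)) {
    txt <- render_report_text(report)
    if ("txt" %in% formats) {
      p <- file.path(out_dir, "report.txt")
      writeLines(txt, p)
      paths <- c(paths, p)
    }
    if ("html" %in% formats) {
      p <- file.path(out_dir, "report.html")
      esc <- gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", txt)))
      writeLines(c("<!DOCTYPE html><html><body><pre>", esc,
                   "</pre></body></html>"), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

render_report_text <- function(report) {
  md <- report$metadata
  locus <- report$locus
  scheme <- report$scheme
  lines <- c(
    "== Plate genotyping report ==",
    "",
    sprintf("locus: %s  %s:%d-%d  (%d bp amplicon)", locus$name,
            locus$chrom, locus$start, locus$end,
            nchar(locus$reference_amplicon)),
    sprintf("reference: %s", locus$reference_amplicon),
    if (nrow(locus$roi)) sprintf("roi: %s",
        paste0(locus$roi$label, "[", locus$roi$start, ",", locus$roi$end,
               ")", collapse = " ")) else "roi: none",
    if (!is.null(locus$donor_diffs)) sprintf("donor: %s",
        paste0(locus$donor_diffs$pos, ":", locus$donor_diffs$ref, ">",
               locus$donor_diffs$alt, collapse = " ")) else "donor: none",
    sprintf("barcode spacer: %s  row linker: %s  column linker: %s",
            scheme$spacer, scheme$row_linker, scheme$column_linker),
    sprintf("parameters: %s",
            paste(names(md$params), unlist(md$params), sep = "=",
                  collapse = " ")),
    "",
    sprintf("wells processed: %d  successfully sequenced: %d  success rate: %.1f%%",
            report$summary$wells_processed, report$summary$wells_sequenced,
            report$summary$success_rate),
    "")
  for (i in seq_len(nrow(report$wells))) {
    w <- report$wells[i, ]
    lines <- c(lines, sprintf("-- well %s: %s (merged reads: %d)", w$well,
                              w$status, w$total_merged_reads))
    if (w$status == "reported") {
      lines <- c(lines, sprintf("   genotype: %s%s", w$genotype_string,
                                if (isTRUE(w$homozygote_flag))
                                  "  [single allele: verify against large-deletion artefact]"
                                else ""))
      called <- w$called_alleles[[1]]
      for (k in seq_len(nrow(called))) {
        a <- called[k, ]
        lines <- c(lines,
                   sprintf("   allele %d: count=%d fraction=%.3f class=%s %s",
                           k, a$count, a$fraction, a$allele_class,
                           a$variant_notation),
                   render_well_alignment(a$sequence, locus), "")
      }
    }
    lines <- c(lines, "")
  }
  lines
}
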