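# File formats: FASTQ/FASTA through Biostrings, BED through rtracklayer.
# All metadata files are plain text, per the protocol's requirement.

#' Read a paired FASTQ run
#'
#' @param fastq1,fastq2 mate FASTQ paths (Phred+33; plain or gzip).
#' @return data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  r1 <- read_fastq_one(fastq1)
  r2 <- read_fastq_one(fastq2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate count mismatch: ", nrow(r1), " reads in '", fastq1,
         "' vs ", nrow(r2), " in '", fastq2, "'")
  }
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = if (length(x)) sub("[\t ].*$", "", names(x)) else character(),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read pairs listed in a path-list metadata file
#'
#' The file holds one pair of whitespace-separated FASTQ paths per line
#' (`#` comments and blank lines allowed); relative paths are resolved
#' against the file's directory.
#'
#' @param path_list_file plain-text file of FASTQ path pairs.
#' @return data frame as [read_fastq_pair()], concatenated over lines.
#' @export
read_fastq_pairs <- function(path_list_file) {
  lines <- readLines(path_list_file, warn = FALSE)
  lines <- trimws(sub("\r$", "", sub("#.*$", "", lines)))
  lines <- lines[nzchar(lines)]
  base <- dirname(path_list_file)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) != 2L) {
      stop("path list line must name exactly two FASTQ files: '", ln, "'")
    }
    paths <- ifelse(file.exists(parts), parts, file.path(base, parts))
    out[[length(out) + 1L]] <- read_fastq_pair(paths[1], paths[2])
  }
  if (!length(out)) {
    return(data.frame(id = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a FASTQ file
#'
#' @param ids,seqs,quals read names, sequences and Phred+33 qualities.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Construct a target locus
#'
#' @param name locus label.
#' @param reference_amplicon expected amplicon sequence (locus primers
#'   included, barcode linkers excluded).
#' @param chrom,start,end genomic interval of the amplicon (0-based
#'   half-open, BED convention).
#' @param roi data frame of regions of interest with columns `label`,
#'   `start`, `end` in 0-based half-open amplicon coordinates.
#' @param donor_diffs optional data frame of expected HDR substitutions
#'   with columns `pos` (0-based amplicon), `ref`, `alt`.
#' @return object of class `target_locus`.
#' @export
target_locus <- function(name, reference_amplicon, chrom = "amplicon",
                         start = 0L, end = NULL, roi = NULL,
                         donor_diffs = NULL) {
  reference_amplicon <- toupper(reference_amplicon)
  if (is.null(end)) end <- start + nchar(reference_amplicon)
  if (end - start != nchar(reference_amplicon)) {
    stop("interval length (", end - start, ") does not match amplicon ",
         "length (", nchar(reference_amplicon), ")")
  }
  if (is.null(roi)) {
    roi <- data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(roi) && any(roi$start < 0 | roi$end > nchar(reference_amplicon) |
                       roi$start >= roi$end)) {
    stop("region(s) of interest fall outside the amplicon")
  }
  if (!is.null(donor_diffs)) {
    stopifnot(all(c("pos", "ref", "alt") %in% names(donor_diffs)))
    ref_at <- substr(rep(reference_amplicon, nrow(donor_diffs)),
                     donor_diffs$pos + 1L, donor_diffs$pos + 1L)
    if (any(ref_at != donor_diffs$ref)) {
      stop("donor_diffs ref base(s) do not match the reference amplicon")
    }
  }
  structure(list(name = name, chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 reference_amplicon = reference_amplicon,
                 roi = roi, donor_diffs = donor_diffs),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat("target_locus '", x$name, "': ", x$chrom, ":", x$start, "-", x$end,
      " (", nchar(x$reference_amplicon), " bp)\n", sep = "")
  if (nrow(x$roi)) {
    cat("  ROIs:", paste0(x$roi$label, "[", x$roi$start, ",", x$roi$end, ")",
                          collapse = ", "), "\n")
  }
  if (!is.null(x$donor_diffs)) {
    cat("  donor:", paste0(x$donor_diffs$pos, ":", x$donor_diffs$ref, ">",
                           x$donor_diffs$alt, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a target-locus BED file
#'
#' The first interval is the amplicon; any further intervals are regions
#' of interest, converted to amplicon-relative coordinates. Coordinates
#' are 0-based half-open throughout.
#'
#' @param bed_path BED file path.
#' @param reference_fasta optional FASTA with the reference amplicon
#'   sequence (first record used).
#' @param donor_diffs optional donor specification; see [target_locus()]
#'   and [read_donor_diffs()].
#' @return a `target_locus` (with an `reference_amplicon` of `N`s when no
#'   FASTA is supplied).
#' @export
read_target_bed <- function(bed_path, reference_fasta = NULL,
                            donor_diffs = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (!length(gr)) stop("BED file '", bed_path, "' is empty")
  amp <- gr[1]
  astart <- GenomicRanges::start(amp) - 1L  # GRanges is 1-based
  aend <- GenomicRanges::end(amp)
  labels <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  roi <- data.frame(label = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (length(gr) > 1L) {
    rest <- gr[-1]
    rs <- GenomicRanges::start(rest) - 1L - astart
    re <- GenomicRanges::end(rest) - astart
    if (any(rs < 0 | re > aend - astart)) {
      stop("region of interest outside the amplicon interval in '",
           bed_path, "'")
    }
    lab <- labels[-1]
    lab[is.na(lab)] <- paste0("roi", seq_len(length(rest)))[is.na(lab)]
    roi <- data.frame(label = lab, start = rs, end = re,
                      stringsAsFactors = FALSE)
  }
  ref <- strrep("N", aend - astart)
  name <- if (!is.na(labels[1])) labels[1] else basename(bed_path)
  if (!is.null(reference_fasta)) {
    fa <- Biostrings::readDNAStringSet(reference_fasta)
    if (!length(fa)) stop("empty FASTA: ", reference_fasta)
    ref <- as.character(fa[[1]])
    if (nchar(ref) != aend - astart) {
      stop("reference amplicon length (", nchar(ref),
           ") does not match the BED amplicon interval (", aend - astart, ")")
    }
  }
  target_locus(name, ref,
               chrom = as.character(GenomicRanges::seqnames(amp)),
               start = astart, end = aend, roi = roi,
               donor_diffs = donor_diffs)
}

#' Read an expected-HDR (donor) substitution file
#'
#' Plain text, one substitution per line: `pos ref alt`, with `pos` the
#' 1-based position in the amplicon (converted to 0-based internally).
#'
#' @param path donor specification file.
#' @return data frame with `pos` (0-based), `ref`, `alt`.
#' @export
read_donor_diffs <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("pos", "ref", "alt"),
                    colClasses = c("integer", "character", "character"))
  data.frame(pos = tab$pos - 1L, ref = toupper(tab$ref),
             alt = toupper(tab$alt), stringsAsFactors = FALSE)
}
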