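# Dual-barcode demultiplexing: every second-round barcoding primer is
# [3 bp spacer][8 bp well barcode][m13-derived linker]; row primers mark one
# end of the molecule and column primers the other, addressing 96 wells.

lcp <- function(x) {
  # longest common prefix of a character vector
  n <- min(nchar(x))
  k <- 0L
  while (k < n && length(unique(substr(x, k + 1L, k + 1L))) == 1L) k <- k + 1L
  substr(x[1], 1L, k)
}

lcs_suffix <- function(x) {
  n <- min(nchar(x))
  k <- 0L
  while (k < n &&
         length(unique(substring(x, nchar(x) - k, nchar(x) - k))) == 1L) {
    k <- k + 1L
  }
  substring(x[1], nchar(x[1]) - k + 1L)
}

read_primer_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (any(grepl("[{\\\\]rtf", lines))) {
    stop("primer file '", path, "' looks like rich text; plain text required")
  }
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("primer file '", path, "' must contain at least two primers")
  }
  parts <- strsplit(lines, "[\t ]+")
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("primer file '", path, "' line(s) without an id and a sequence: ",
         paste(which(bad), collapse = ", "))
  }
  ids <- vapply(parts, `[`, character(1), 1L)
  seqs <- toupper(vapply(parts, `[`, character(1), 2L))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("primer file '", path, "' contains non-ACGT characters")
  }
  data.frame(id = ids, full_sequence = seqs, stringsAsFactors = FALSE)
}

decompose_scheme <- function(fwd, rev) {
  spacer <- lcp(c(fwd$full_sequence, rev$full_sequence))
  groups <- list(row = fwd, column = rev)
  linkers <- lapply(groups, function(g) lcs_suffix(g$full_sequence))
  primers <- Map(function(g, linker, group) {
    bc <- substr(g$full_sequence, nchar(spacer) + 1L,
                 nchar(g$full_sequence) - nchar(linker))
    data.frame(id = g$id, group = group, spacer = spacer, barcode = bc,
               linker = linker, full_sequence = g$full_sequence,
               stringsAsFactors = FALSE)
  }, groups, linkers, names(groups))
  primers
}

#' Load a dual-barcode plate scheme from primer files
#'
#' Reads the forward (row) and reverse (column) barcoding primer files and
#' decomposes every oligo into spacer + well barcode + linker. The spacer
#' is the longest common prefix over all primers; each group's linker is
#' its longest common suffix; the barcode is what remains.
#'
#' @param fwd_primer_file,rev_primer_file plain-text files, one `id
#'   sequence` pair per line (tab- or whitespace-separated, `#` comments
#'   allowed).
#' @return an object of class `barcode_scheme`: a list with `primers`
#'   (data frame of all decomposed primers), `spacer`, `row_linker`,
#'   `column_linker`, `barcode_length`, and `wells` (the 96-well address
#'   table).
#' @examples
#' scheme <- default_scheme()
#' scheme$spacer
#' nrow(scheme$wells)
#' @export
load_scheme <- function(fwd_primer_file, rev_primer_file) {
  fwd <- read_primer_file(fwd_primer_file)
  rev <- read_primer_file(rev_primer_file)
  parts <- decompose_scheme(fwd, rev)
  primers <- rbind(parts$row, parts$column)
  bl <- unique(nchar(primers$barcode))
  if (length(bl) != 1L || bl < 1L) {
    stop("barcode length is not identical across primers (got lengths ",
         paste(sort(bl), collapse = ", "), ")")
  }
  for (g in split(primers, primers$group)) {
    if (anyDuplicated(g$barcode)) {
      stop("duplicate barcode within group '", g$group[1], "'")
    }
  }
  rows <- parts$row$id
  cols <- parts$column$id
  wells <- expand.grid(row_index = seq_along(rows),
                       column_index = seq_along(cols))
  wells <- wells[order(wells$row_index, wells$column_index), , drop = FALSE]
  wells$row_id <- rows[wells$row_index]
  wells$column_id <- cols[wells$column_index]
  wells$row <- LETTERS[wells$row_index]
  wells$column <- wells$column_index
  wells$label <- sprintf("%s%02d", wells$row, wells$column)
  rownames(wells) <- NULL
  structure(list(primers = primers,
                 spacer = parts$row$spacer[1],
                 row_linker = parts$row$linker[1],
                 column_linker = parts$column$linker[1],
                 barcode_length = bl,
                 wells = wells),
            class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("barcode_scheme:", sum(x$primers$group == "row"), "row x",
      sum(x$primers$group == "column"), "column primers;",
      nrow(x$wells), "wells\n")
  cat("  spacer:", x$spacer, " barcode length:", x$barcode_length, "\n")
  cat("  row linker:", x$row_linker, "\n")
  cat("  column linker:", x$column_linker, "\n")
  invisible(x)
}

#' Bundled 8 x 12 barcoding primer scheme
#'
#' Loads the standard 96-well scheme (8 row + 12 column oligos with the GAT
#' spacer, 8 bp barcodes and m13-derived linkers) shipped with the package.
#'
#' @return a `barcode_scheme`.
#' @export
default_scheme <- function() {
  load_scheme(system.file("extdata", "barcode_primers_fwd.txt",
                          package = "ampliwell"),
              system.file("extdata", "barcode_primers_rev.txt",
                          package = "ampliwell"))
}

scheme_group <- function(scheme, group) {
  scheme$primers[scheme$primers$group == group, , drop = FALSE]
}

prefix_length <- function(scheme, group) {
  linker <- if (group == "row") scheme$row_linker else scheme$column_linker
  nchar(scheme$spacer) + scheme$barcode_length + nchar(linker)
}

#' Assign read prefixes to barcodes within one group
#'
#' Matches the fixed-offset spacer + barcode + linker window at the start
#' of each read against one primer group. The spacer and the first five
#' linker bases are sanity gates (at most one mismatch each); the barcode
#' itself must be within `max_mismatch` of exactly one barcode in the
#' group.
#'
#' @param prefixes character vector of read 5' sequences.
#' @param group `"row"` or `"column"`.
#' @param scheme a [load_scheme()] result.
#' @param max_mismatch maximum Hamming distance allowed on the barcode.
#' @return data frame with columns `id` (primer id or `NA`), `mismatches`,
#'   and `reason` (`"none"`, `"no_spacer"`, `"ambiguous_barcode"`,
#'   `"too_many_mismatches"`).
#' @export
assign_barcode <- function(prefixes, group = c("row", "column"), scheme,
                           max_mismatch = 1L) {
  group <- match.arg(group)
  g <- scheme_group(scheme, group)
  linker <- if (group == "row") scheme$row_linker else scheme$column_linker
  sl <- nchar(scheme$spacer)
  bl <- scheme$barcode_length
  gate_len <- min(5L, nchar(linker))
  need <- sl + bl + gate_len

  n <- length(prefixes)
  id <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  reason <- rep("none", n)

  short <- nchar(prefixes) < need
  reason[short] <- "no_spacer"

  spacer_obs <- substr(prefixes, 1L, sl)
  gate_obs <- substr(prefixes, sl + bl + 1L, sl + bl + gate_len)
  spacer_ok <- hamming_matrix_cpp(spacer_obs, scheme$spacer)[, 1] <= 1L
  gate_ok <- hamming_matrix_cpp(gate_obs, substr(linker, 1L, gate_len))[, 1] <= 1L
  gate_fail <- !short & (!spacer_ok | !gate_ok | is.na(spacer_ok) | is.na(gate_ok))
  gate_fail[is.na(gate_fail)] <- TRUE
  reason[!short & gate_fail] <- "no_spacer"

  live <- !short & !gate_fail
  if (any(live)) {
    windows <- substr(prefixes[live], sl + 1L, sl + bl)
    hit <- match(windows, g$barcode)
    exact <- !is.na(hit)
    idx_live <- which(live)
    id[idx_live[exact]] <- g$id[hit[exact]]
    mm[idx_live[exact]] <- 0L
    # exact matches cannot be ambiguous: barcodes are unique within a group
    fb <- idx_live[!exact]
    if (length(fb)) {
      d <- hamming_matrix_cpp(windows[!exact], g$barcode)
      within <- d <= max_mismatch
      nq <- rowSums(within)
      best <- max.col(-d, ties.method = "first")
      one <- nq == 1L
      id[fb[one]] <- g$id[best[one]]
      mm[fb[one]] <- d[cbind(which(one), best[one])]
      reason[fb[nq == 0L]] <- "too_many_mismatches"
      reason[fb[nq >= 2L]] <- "ambiguous_barcode"
    }
  }
  data.frame(id = id, mismatches = mm, reason = reason,
             stringsAsFactors = FALSE)
}

REASON_PRIORITY <- c("ambiguous_barcode", "too_many_mismatches", "no_spacer")

pick_fail_reason <- function(...) {
  reasons <- c(...)
  reasons <- reasons[reasons != "none"]
  if (!length(reasons)) return("none")
  REASON_PRIORITY[min(match(reasons, REASON_PRIORITY))]
}

#' Demultiplex paired reads to wells
#'
#' Assigns each read pair to a well by matching one mate against the row
#' barcodes and the other against the column barcodes. Both mate-role
#' orientations are tried (library ligation is non-directional); the
#' orientation with fewer total barcode mismatches wins, and an exact tie
#' between two valid orientations leaves the pair unassigned. On success
#' the spacer + barcode + linker prefix is trimmed from both mates.
#'
#' @param pairs data frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (as returned by [read_fastq_pair()]).
#' @param scheme a [load_scheme()] result.
#' @param max_mismatch maximum Hamming distance per barcode.
#' @return the input data frame plus columns `well`, `orientation`
#'   (`"row_first"`, `"column_first"`, or `"none"`), `mismatches`,
#'   `fail_reason`, and trimmed `trim_seq1`/`trim_qual1`/`trim_seq2`/
#'   `trim_qual2` (NA when unassigned).
#' @export
demultiplex_pairs <- function(pairs, scheme, max_mismatch = 1L) {
  n <- nrow(pairs)
  r1 <- assign_barcode(pairs$seq1, "row", scheme, max_mismatch)
  c1 <- assign_barcode(pairs$seq1, "column", scheme, max_mismatch)
  r2 <- assign_barcode(pairs$seq2, "row", scheme, max_mismatch)
  c2 <- assign_barcode(pairs$seq2, "column", scheme, max_mismatch)

  ok_rf <- !is.na(r1$id) & !is.na(c2$id)
  ok_cf <- !is.na(c1$id) & !is.na(r2$id)
  mm_rf <- r1$mismatches + c2$mismatches
  mm_cf <- c1$mismatches + r2$mismatches

  orientation <- rep("none", n)
  orientation[ok_rf & !ok_cf] <- "row_first"
  orientation[!ok_rf & ok_cf] <- "column_first"
  both <- ok_rf & ok_cf
  orientation[both & (mm_rf < mm_cf)] <- "row_first"
  orientation[both & (mm_cf < mm_rf)] <- "column_first"
  # both valid with equal mismatches -> ambiguous, stays "none"

  row_id <- ifelse(orientation == "row_first", r1$id,
                   ifelse(orientation == "column_first", r2$id, NA))
  col_id <- ifelse(orientation == "row_first", c2$id,
                   ifelse(orientation == "column_first", c1$id, NA))
  key <- paste(row_id, col_id)
  wk <- paste(scheme$wells$row_id, scheme$wells$column_id)
  well <- scheme$wells$label[match(key, wk)]

  mismatches <- ifelse(orientation == "row_first", mm_rf,
                       ifelse(orientation == "column_first", mm_cf, NA))

  fail_reason <- rep("none", n)
  un <- which(orientation == "none")
  for (i in un) {
    fail_reason[i] <- if (ok_rf[i] && ok_cf[i]) {
      "ambiguous_barcode"
    } else {
      pick_fail_reason(r1$reason[i], c1$reason[i], r2$reason[i], c2$reason[i])
    }
  }

  row_len <- prefix_length(scheme, "row")
  col_len <- prefix_length(scheme, "column")
  t1 <- ifelse(orientation == "row_first", row_len,
               ifelse(orientation == "column_first", col_len, NA))
  t2 <- ifelse(orientation == "row_first", col_len,
               ifelse(orientation == "column_first", row_len, NA))
  assigned <- orientation != "none"
  trim_seq1 <- trim_qual1 <- trim_seq2 <- trim_qual2 <- rep(NA_character_, n)
  trim_seq1[assigned] <- substring(pairs$seq1[assigned], t1[assigned] + 1L)
  trim_qual1[assigned] <- substring(pairs$qual1[assigned], t1[assigned] + 1L)
  trim_seq2[assigned] <- substring(pairs$seq2[assigned], t2[assigned] + 1L)
  trim_qual2[assigned] <- substring(pairs$qual2[assigned], t2[assigned] + 1L)
  # reorient to the plate frame: trimmed mate 1 always carries the row
  # (forward) end, so downstream merged fragments sit on the reference
  # strand regardless of which mate the ligation put first
  cf <- orientation == "column_first"
  if (any(cf)) {
    tmp_s <- trim_seq1[cf]; tmp_q <- trim_qual1[cf]
    trim_seq1[cf] <- trim_seq2[cf]; trim_qual1[cf] <- trim_qual2[cf]
    trim_seq2[cf] <- tmp_s; trim_qual2[cf] <- tmp_q
  }

  out <- pairs
  out$well <- well
  out$orientation <- orientation
  out$mismatches <- mismatches
  out$fail_reason <- fail_reason
  out$trim_seq1 <- trim_seq1
  out$trim_qual1 <- trim_qual1
  out$trim_seq2 <- trim_seq2
  out$trim_qual2 <- trim_qual2
  out
}

#' Demultiplex one read pair
#'
#' Single-pair convenience wrapper around [demultiplex_pairs()].
#'
#' @param seq1,qual1,seq2,qual2 mate sequences and Phred+33 qualities.
#' @param scheme a [load_scheme()] result.
#' @param max_mismatch maximum Hamming distance per barcode.
#' @param id read pair identifier.
#' @return a one-row data frame; see [demultiplex_pairs()].
#' @export
demultiplex_pair <- function(seq1, seq2, scheme,
                             qual1 = strrep("I", nchar(seq1)),
                             qual2 = strrep("I", nchar(seq2)),
                             max_mismatch = 1L, id = "pair1") {
  demultiplex_pairs(data.frame(id = id, seq1 = seq1, qual1 = qual1,
                               seq2 = seq2, qual2 = qual2,
                               stringsAsFactors = FALSE),
                    scheme, max_mismatch)
}

#' Demultiplex a FASTQ pair into per-well collections
#'
#' Runs [demultiplex_pairs()] over a full paired FASTQ run and tallies
#' per-well and unassigned counts. Assigned + unassigned always equals the
#' number of input pairs.
#'
#' @param fastq1,fastq2 paths to the mate FASTQ files (plain or gzip).
#' @param scheme a [load_scheme()] result.
#' @param max_mismatch maximum Hamming distance per barcode.
#' @param out_dir if non-NULL, trimmed per-well FASTQ files
#'   (`<label>_R1.fastq.gz` / `_R2`) and a `demux_counts.tsv` are written
#'   there.
#' @return list with `assignments` (the full assignment table), `counts`
#'   (well, assigned, fraction; all scheme wells, zeros included), and
#'   `unassigned` (count).
#' @export
demultiplex_run <- function(fastq1, fastq2, scheme, max_mismatch = 1L,
                            out_dir = NULL) {
  pairs <- read_fastq_pair(fastq1, fastq2)
  asg <- demultiplex_pairs(pairs, scheme, max_mismatch)
  tab <- table(factor(asg$well, levels = scheme$wells$label))
  counts <- data.frame(well = names(tab), assigned = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts$fraction <- if (nrow(asg)) counts$assigned / nrow(asg) else 0
  unassigned <- sum(is.na(asg$well))
  stopifnot(sum(counts$assigned) + unassigned == nrow(asg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- !is.na(asg$well)
    for (w in unique(asg$well[keep])) {
      sel <- which(asg$well == w)
      write_fastq(asg$id[sel], asg$trim_seq1[sel], asg$trim_qual1[sel],
                  file.path(out_dir, paste0(w, "_R1.fastq.gz")))
      write_fastq(asg$id[sel], asg$trim_seq2[sel], asg$trim_qual2[sel],
                  file.path(out_dir, paste0(w, "_R2.fastq.gz")))
    }
    write.table(counts, file.path(out_dir, "demux_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(assignments = asg, counts = counts, unassigned = unassigned)
}
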