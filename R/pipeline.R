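# Pipeline driver: demultiplex -> merge -> align/classify -> genotype ->
# report, with per-stage accounting. Configuration is a plain list, read
# from a key-value text file or built directly.

#' Build a run configuration
#'
#' @param fastq1,fastq2 paired FASTQ paths (alternative:
#'   `fastq_paths` file).
#' @param fastq_paths plain-text file listing FASTQ pairs (one pair per
#'   line); overrides `fastq1`/`fastq2`.
#' @param fwd_primers,rev_primers barcoding primer files.
#' @param bed target-locus BED file.
#' @param reference reference amplicon FASTA.
#' @param donor optional donor substitution file ([read_donor_diffs()]).
#' @param out_dir optional output directory for the report files.
#' @param max_mismatch,min_overlap,max_mismatch_ratio,min_reads,
#'   min_allele_fraction,ploidy numeric pipeline parameters (see the
#'   stage functions).
#' @param scoring alignment scoring list.
#' @return a `run_config` list.
#' @export
run_config <- function(fastq1 = NULL, fastq2 = NULL, fastq_paths = NULL,
                       fwd_primers, rev_primers, bed, reference,
                       donor = NULL, out_dir = NULL,
                       max_mismatch = 1L, min_overlap = 10L,
                       max_mismatch_ratio = 0.25, min_reads = 10L,
                       min_allele_fraction = 0.15, ploidy = 2L,
                       scoring = default_scoring()) {
  cfg <- list(fastq1 = fastq1, fastq2 = fastq2, fastq_paths = fastq_paths,
              fwd_primers = fwd_primers, rev_primers = rev_primers,
              bed = bed, reference = reference, donor = donor,
              out_dir = out_dir, max_mismatch = as.integer(max_mismatch),
              min_overlap = as.integer(min_overlap),
              max_mismatch_ratio = max_mismatch_ratio,
              min_reads = as.integer(min_reads),
              min_allele_fraction = min_allele_fraction,
              ploidy = as.integer(ploidy), scoring = scoring)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a plain-text key-value file
#'
#' One `key = value` (or `key: value`) entry per line, `#` comments
#' allowed; keys match the arguments of [run_config()]. Relative paths
#' are resolved against the config file's directory.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", sub("#.*$", "", lines)))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)[ \t]*[:=][ \t]*(.*)$",
                                  lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  args <- as.list(vals)
  names(args) <- keys
  num <- c("max_mismatch", "min_overlap", "max_mismatch_ratio", "min_reads",
           "min_allele_fraction", "ploidy")
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  base <- dirname(path)
  pathkeys <- c("fastq1", "fastq2", "fastq_paths", "fwd_primers",
                "rev_primers", "bed", "reference", "donor")
  for (k in intersect(names(args), pathkeys)) {
    if (!file.exists(args[[k]])) args[[k]] <- file.path(base, args[[k]])
  }
  do.call(run_config, args)
}

check_config_files <- function(config) {
  need <- c("fwd_primers", "rev_primers", "bed", "reference")
  if (is.null(config$fastq_paths)) need <- c("fastq1", "fastq2", need)
  else need <- c("fastq_paths", need)
  if (!is.null(config$donor)) need <- c(need, "donor")
  for (k in need) {
    if (is.null(config[[k]])) stop("run_config is missing '", k, "'")
    if (!file.exists(config[[k]])) {
      stop("configured ", k, " file does not exist: ", config[[k]])
    }
  }
}

#' Run the full plate genotyping pipeline
#'
#' Demultiplexes the run to wells, merges mate pairs into fragments,
#' collapses and classifies per-well alleles, calls genotypes, and
#' assembles (and, when `out_dir` is set, writes) the plate report.
#' Per-stage counts are logged to stderr; every input pair ends up in
#' exactly one of assigned-and-merged, assigned-unmerged, or unassigned.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging.
#' @return object of class `plate_report`: list with `wells` (per-well
#'   calls), `alleles` (long allele table), `summary`
#'   ([summarize_plate()]), `counts` (stage totals), `metadata`, `locus`,
#'   `scheme`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  check_config_files(config)
  log_msg <- function(...) if (!quiet) message("[ampliwell] ", ...)

  scheme <- load_scheme(config$fwd_primers, config$rev_primers)
  donor <- if (!is.null(config$donor)) read_donor_diffs(config$donor)
  locus <- read_target_bed(config$bed, config$reference, donor)

  pairs <- if (!is.null(config$fastq_paths)) {
    read_fastq_pairs(config$fastq_paths)
  } else {
    read_fastq_pair(config$fastq1, config$fastq2)
  }
  log_msg("input: ", nrow(pairs), " read pairs")

  asg <- demultiplex_pairs(pairs, scheme, config$max_mismatch)
  n_assigned <- sum(!is.na(asg$well))
  log_msg("demux: ", n_assigned, " assigned, ",
          nrow(asg) - n_assigned, " unassigned")

  merged <- merge_assigned(asg, config$min_overlap,
                           config$max_mismatch_ratio)
  n_merged <- sum(merged$merged)
  log_msg("merge: ", n_merged, " merged, ", nrow(merged) - n_merged,
          " unmerged")

  input_by_well <- table(factor(asg$well, levels = scheme$wells$label))
  wells <- vector("list", nrow(scheme$wells))
  alleles_long <- list()
  for (i in seq_len(nrow(scheme$wells))) {
    w <- scheme$wells$label[i]
    frag <- merged$sequence[merged$well == w & merged$merged]
    alle <- collapse_alleles(frag, locus, config$scoring)
    wells[[i]] <- call_genotype(alle, config$ploidy, config$min_reads,
                                config$min_allele_fraction, well = w,
                                n_input_reads = as.integer(input_by_well[[w]]))
    if (nrow(alle)) {
      alleles_long[[length(alleles_long) + 1L]] <- data.frame(
        well = w, rank = seq_len(nrow(alle)),
        alle[, c("sequence", "count", "fraction", "allele_class",
                 "variant_notation")],
        called = seq_len(nrow(alle)) %in%
          seq_len(wells[[i]]$n_called) &
          alle$fraction >= config$min_allele_fraction &
          wells[[i]]$status == "reported",
        stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, wells)
  alleles_long <- if (length(alleles_long)) do.call(rbind, alleles_long)
    else data.frame(well = character(), rank = integer(),
                    sequence = character(), count = integer(),
                    fraction = numeric(), allele_class = character(),
                    variant_notation = character(), called = logical(),
                    stringsAsFactors = FALSE)
  summary <- summarize_plate(wells)
  log_msg("calls: ", summary$wells_sequenced, "/",
          summary$wells_processed, " wells reported (",
          sprintf("%.1f", summary$success_rate), "%)")

  report <- structure(list(
    wells = wells, alleles = alleles_long, summary = summary,
    counts = list(input_pairs = nrow(pairs), assigned = n_assigned,
                  unassigned = nrow(pairs) - n_assigned,
                  merged = n_merged, unmerged = nrow(merged) - n_merged),
    metadata = list(params = config[c("max_mismatch", "min_overlap",
                                      "max_mismatch_ratio", "min_reads",
                                      "min_allele_fraction", "ploidy")]),
    locus = locus, scheme = scheme), class = "plate_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    manifest <- c(sprintf("input_pairs\t%d", nrow(pairs)),
                  sprintf("assigned\t%d", n_assigned),
                  sprintf("merged\t%d", n_merged),
                  sprintf("wells_processed\t%d", summary$wells_processed),
                  sprintf("wells_sequenced\t%d", summary$wells_sequenced),
                  sprintf("success_rate\t%.1f", summary$success_rate))
    writeLines(manifest, file.path(config$out_dir, "run_manifest.tsv"))
  }
  report
}

#' @export
print.plate_report <- function(x, ...) {
  cat("plate_report:", x$counts$input_pairs, "pairs;",
      x$counts$assigned, "assigned;", x$counts$merged, "merged\n")
  cat("  wells processed:", x$summary$wells_processed,
      " sequenced:", x$summary$wells_sequenced,
      sprintf(" success rate: %.1f%%\n", x$summary$success_rate))
  gt <- table(x$wells$genotype_string[x$wells$status == "reported"])
  if (length(gt)) {
    cat("  genotypes:\n")
    for (g in names(sort(gt, decreasing = TRUE))) {
      cat("    ", g, ": ", gt[[g]], "\n", sep = "")
    }
  }
  invisible(x)
}
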