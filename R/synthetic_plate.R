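# Synthetic 96-well plate simulator: emits paired FASTQ with the real
# library-molecule structure -- [spacer + row barcode + row linker] +
# allele + revcomp([spacer + column barcode + column linker]) -- read as
# 2 x 250 bp mates with i.i.d. substitution errors, plus a truth table.
# This is the end-to-end test harness for every other module.

DEMO_AMPLICON <- paste0(
  "AGCACGATAGCCGTGCATTGCGAGTTTATACTCCCACTCTATTAAGCATAACACCACCCAGCGGACGACT",
  "AATAAGGAGTCAGGGGTCTCGCGACTAGACGTTTGATCTTTTACCGCATGCAGGCACGCCGACGATGGCA",
  "TATACATGCCCACCGCATGAACATCGAATTGAGGTCGCTACTATGCCTTTGTGGAGAGCACTGTCTAGCC",
  "CGTGTCGACAGCCAACTACATTACCATGAACAGGTTGGTAGTATAGAAGGGTTGACCCGATGTCGCCATA",
  "ATGTTTGATCAAGGCGTAAGAACGTTAGTAACCGGTTCTGTATACGATAATCAGGACCGGCTGGAAGAGT")

#' Bundled synthetic demonstration locus
#'
#' A fixed 350 bp synthetic amplicon (random composition, no biological
#' provenance) with a 20 bp gRNA region of interest around the centre and
#' a single programmed donor substitution at the cut site.
#'
#' @return a [target_locus()].
#' @export
demo_locus <- function() {
  ref <- DEMO_AMPLICON
  cut <- 175L
  donor_ref <- substr(ref, cut + 1L, cut + 1L)
  donor_alt <- setdiff(DNA_BASES, donor_ref)[1]
  target_locus(
    name = "synthetic_demo",
    reference_amplicon = ref,
    chrom = "chrS", start = 1000L, end = 1000L + 350L,
    roi = data.frame(label = c("gRNA", "edit"),
                     start = c(cut - 17L, cut), end = c(cut + 3L, cut + 1L),
                     stringsAsFactors = FALSE),
    donor_diffs = data.frame(pos = cut, ref = donor_ref, alt = donor_alt,
                             stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults emulate a typical screening run: 2 x 250 bp MiSeq reads, a
#' log-normal read depth with median 500 pairs per well, a small fraction
#' of shallow and empty wells so threshold behaviour is exercised, NHEJ
#' indels with geometric size (mean 3, deletions twice as likely as
#' insertions), and HDR outcomes rarer than NHEJ.
#'
#' @param seed integer seed; fully determines the simulated plate.
#' @param locus a [target_locus()] with a cut-site ROI (and `donor_diffs`
#'   when HDR outcomes have non-zero probability).
#' @param read_length mate length in bp.
#' @param wells well labels to simulate (default all 96).
#' @param genotype_probabilities named probabilities over the seven
#'   outcome categories.
#' @param indel_mean_size mean of the geometric indel-size distribution.
#' @param deletion_fraction probability that an NHEJ indel is a deletion.
#' @param substitution_error_rate per-base sequencing error probability.
#' @param reads_per_well_median,reads_per_well_sdlog log-normal read-depth
#'   parameters.
#' @param low_read_probability fraction of wells drawn instead from a
#'   shallow Poisson(5) depth.
#' @param empty_well_probability fraction of wells with no reads at all.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       locus = demo_locus(),
                       read_length = 250L,
                       wells = NULL,
                       genotype_probabilities = c(
                         "WT/WT" = 0.25, "WT/indel" = 0.25,
                         "indel/indel" = 0.20, "HDR/WT" = 0.10,
                         "HDR/indel" = 0.10, "HDR/HDR" = 0.05,
                         "complex" = 0.05),
                       indel_mean_size = 3,
                       deletion_fraction = 2 / 3,
                       substitution_error_rate = 0.001,
                       reads_per_well_median = 500,
                       reads_per_well_sdlog = 0.6,
                       low_read_probability = 0.03,
                       empty_well_probability = 0.02) {
  stopifnot(abs(sum(genotype_probabilities) - 1) < 1e-9,
            read_length > 0, indel_mean_size >= 1)
  structure(list(seed = as.integer(seed), locus = locus,
                 read_length = as.integer(read_length), wells = wells,
                 genotype_probabilities = genotype_probabilities,
                 indel_mean_size = indel_mean_size,
                 deletion_fraction = deletion_fraction,
                 substitution_error_rate = substitution_error_rate,
                 reads_per_well_median = reads_per_well_median,
                 reads_per_well_sdlog = reads_per_well_sdlog,
                 low_read_probability = low_read_probability,
                 empty_well_probability = empty_well_probability),
            class = "sim_config")
}

cut_site <- function(locus) {
  if (!nrow(locus$roi)) stop("locus has no region of interest (cut site)")
  r <- locus$roi[locus$roi$label == "edit", , drop = FALSE]
  if (!nrow(r)) r <- locus$roi[1, , drop = FALSE]
  as.integer(floor((r$start[1] + r$end[1]) / 2))
}

sample_indel_size <- function(mean_size) {
  rgeom(1L, 1 / mean_size) + 1L
}

#' Simulate a single allele sequence
#'
#' @param locus a [target_locus()].
#' @param outcome `"WT"`, `"HDR"`, `"NHEJ_indel"`, or `"complex"` (donor
#'   substitutions plus an insertion).
#' @param indel_mean_size,deletion_fraction NHEJ indel model parameters.
#' @return the allele sequence.
#' @export
simulate_allele <- function(locus, outcome, indel_mean_size = 3,
                            deletion_fraction = 2 / 3) {
  ref <- locus$reference_amplicon
  apply_donor <- function(s) {
    d <- locus$donor_diffs
    if (is.null(d) || !nrow(d)) {
      stop("HDR/complex outcome requested but the locus has no donor_diffs")
    }
    for (i in seq_len(nrow(d))) {
      substr(s, d$pos[i] + 1L, d$pos[i] + 1L) <- d$alt[i]
    }
    s
  }
  insert_at <- function(s, pos, ins) {
    paste0(substr(s, 1L, pos), ins, substring(s, pos + 1L))
  }
  cut <- cut_site(locus)
  switch(outcome,
    WT = ref,
    HDR = apply_donor(ref),
    NHEJ_indel = {
      size <- sample_indel_size(indel_mean_size)
      pos <- cut + sample(-3:3, 1L)
      if (runif(1) < deletion_fraction) {
        pos <- max(1L, min(pos, nchar(ref) - size - 1L))
        paste0(substr(ref, 1L, pos), substring(ref, pos + size + 1L))
      } else {
        ins <- paste(sample(DNA_BASES, size, replace = TRUE), collapse = "")
        insert_at(ref, max(1L, min(pos, nchar(ref) - 1L)), ins)
      }
    },
    complex = {
      # insertion (never a deletion) so the indel cannot erase the donor base
      s <- apply_donor(ref)
      size <- sample_indel_size(indel_mean_size)
      pos <- cut + sample(4:8, 1L)
      ins <- paste(sample(DNA_BASES, size, replace = TRUE), collapse = "")
      insert_at(s, min(pos, nchar(s) - 1L), ins)
    },
    stop("unknown outcome '", outcome, "'"))
}

outcome_alleles <- function(category) {
  switch(category,
    "WT/WT" = c("WT", "WT"),
    "WT/indel" = c("WT", "NHEJ_indel"),
    "indel/indel" = c("NHEJ_indel", "NHEJ_indel"),
    "HDR/WT" = c("HDR", "WT"),
    "HDR/indel" = c("HDR", "NHEJ_indel"),
    "HDR/HDR" = c("HDR", "HDR"),
    "complex" = c("complex", "WT"),
    stop("unknown genotype category '", category, "'"))
}

class_of_outcome <- c(WT = "WT", HDR = "HDR", NHEJ_indel = "NHEJ_indel",
                      complex = "complex")

#' Build the full library molecule for an allele in a well
#'
#' `[spacer + row barcode + row linker] + allele + revcomp(spacer + column
#' barcode + column linker)`, the second-round PCR product that gets
#' sequenced.
#'
#' @param allele allele sequence.
#' @param well well label (e.g. `"A01"`).
#' @param scheme a [load_scheme()] result.
#' @return the molecule sequence (plus strand).
#' @export
build_library_molecule <- function(allele, well, scheme) {
  w <- scheme$wells[scheme$wells$label == well, , drop = FALSE]
  if (!nrow(w)) stop("unknown well '", well, "'")
  p <- scheme$primers
  rowp <- p$full_sequence[p$id == w$row_id]
  colp <- p$full_sequence[p$id == w$column_id]
  paste0(rowp, allele, revcomp(colp))
}

apply_sequencing_errors <- function(seqs, error_rate, base_qual = "H",
                                    err_qual = "+") {
  quals <- strrep(base_qual, nchar(seqs))
  if (error_rate <= 0) return(list(seq = seqs, qual = quals))
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      orig <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
      substr(quals[i], p, p) <- err_qual
    }
  }
  list(seq = seqs, qual = quals)
}

#' Simulate read pairs from one library molecule
#'
#' Mate 1 is the first `read_length` bases of the emitted strand, mate 2
#' the reverse complement of its last `read_length` bases; each pair is
#' emitted from the plus or minus strand with probability 1/2
#' (non-directional adaptor ligation). Substitution errors are i.i.d. at
#' `error_rate`; erroneous bases get a low quality (Q10) against a Q39
#' baseline.
#'
#' @param molecule a [build_library_molecule()] product.
#' @param n_pairs number of read pairs.
#' @param read_length mate length.
#' @param error_rate per-base substitution probability.
#' @param id_prefix read-name prefix.
#' @return data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
simulate_reads <- function(molecule, n_pairs, read_length = 250L,
                           error_rate = 0, id_prefix = "read") {
  if (n_pairs == 0L) {
    return(data.frame(id = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), stringsAsFactors = FALSE))
  }
  L <- min(read_length, nchar(molecule))
  strands <- c(molecule, revcomp(molecule))
  flip <- runif(n_pairs) < 0.5
  tmpl <- strands[flip + 1L]
  m1 <- substr(tmpl, 1L, L)
  m2 <- revcomp(substring(tmpl, nchar(molecule) - L + 1L))
  e1 <- apply_sequencing_errors(m1, error_rate)
  e2 <- apply_sequencing_errors(m2, error_rate)
  data.frame(id = sprintf("%s_%04d", id_prefix, seq_len(n_pairs)),
             seq1 = e1$seq, qual1 = e1$qual, seq2 = e2$seq, qual2 = e2$qual,
             stringsAsFactors = FALSE)
}

#' Simulate a whole barcoded plate
#'
#' Draws a genotype category, allele pair, and read depth for every well,
#' emits error-bearing read pairs through the full library-molecule
#' structure, shuffles them into sequencer order, and records the truth.
#'
#' @param config a [sim_config()].
#' @param scheme a [load_scheme()] result (default [default_scheme()]).
#' @param reads_per_well optional integer vector (recycled over wells)
#'   overriding the read-depth model -- used for threshold sweeps.
#' @return list with `reads` (data frame: `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), `truth` (one row per well: `well`, `category`,
#'   `allele1_seq`, `allele1_class`, `allele2_seq`, `allele2_class`,
#'   `genotype_string` (canonical order), `n_reads`), and the `config` /
#'   `scheme` used.
#' @export
simulate_plate <- function(config, scheme = default_scheme(),
                           reads_per_well = NULL) {
  set.seed(config$seed)
  locus <- config$locus
  wells <- config$wells
  if (is.null(wells)) wells <- scheme$wells$label
  nw <- length(wells)
  categories <- sample(names(config$genotype_probabilities), nw,
                       replace = TRUE, prob = config$genotype_probabilities)
  if (is.null(reads_per_well)) {
    n_reads <- as.integer(round(rlnorm(nw,
                                       log(config$reads_per_well_median),
                                       config$reads_per_well_sdlog)))
    shallow <- runif(nw) < config$low_read_probability
    n_reads[shallow] <- rpois(sum(shallow), 5)
    n_reads[runif(nw) < config$empty_well_probability] <- 0L
  } else {
    n_reads <- as.integer(rep_len(reads_per_well, nw))
  }
  truth <- vector("list", nw)
  reads <- vector("list", nw)
  for (i in seq_len(nw)) {
    outcomes <- outcome_alleles(categories[i])
    a1 <- simulate_allele(locus, outcomes[1], config$indel_mean_size,
                          config$deletion_fraction)
    a2 <- simulate_allele(locus, outcomes[2], config$indel_mean_size,
                          config$deletion_fraction)
    cls <- class_of_outcome[outcomes]
    truth[[i]] <- data.frame(
      well = wells[i], category = categories[i],
      allele1_seq = a1, allele1_class = cls[1],
      allele2_seq = a2, allele2_class = cls[2],
      genotype_string = genotype_key(paste(cls, collapse = "/")),
      n_reads = n_reads[i], stringsAsFactors = FALSE)
    if (n_reads[i] == 0L) next
    pick <- rbinom(1L, n_reads[i], 0.5)
    n_a <- c(pick, n_reads[i] - pick)
    per_allele <- list()
    for (k in 1:2) {
      if (n_a[k] == 0L) next
      mol <- build_library_molecule(c(a1, a2)[k], wells[i], scheme)
      if (nchar(mol) > 2L * config$read_length - 10L) {
        warning("well ", wells[i], ": molecule (", nchar(mol),
                " bp) too long to merge at 2x", config$read_length,
                " bp; skipped")
        next
      }
      per_allele[[k]] <- simulate_reads(
        mol, n_a[k], config$read_length, config$substitution_error_rate,
        id_prefix = sprintf("sim_%s_a%d", wells[i], k))
    }
    reads[[i]] <- do.call(rbind, per_allele)
  }
  reads <- do.call(rbind, c(reads[!vapply(reads, is.null, logical(1))],
                            list(simulate_reads("ACGT", 0L))))
  if (nrow(reads)) {
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
  }
  truth <- do.call(rbind, truth)
  list(reads = reads, truth = truth, config = config, scheme = scheme)
}

#' Write a simulated plate as a complete pipeline fixture
#'
#' Emits gzipped paired FASTQ, the truth table, and the run's plain-text
#' metadata files (FASTQ path list, forward/reverse primer files, target
#' BED, reference FASTA, donor spec), so the directory is a self-contained
#' input for [run_pipeline()].
#'
#' @param sim a [simulate_plate()] result.
#' @param out_dir output directory.
#' @return invisibly, a named list of the written paths.
#' @export
write_simulated_plate <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  locus <- sim$config$locus
  p <- function(...) file.path(out_dir, ...)
  write_fastq(sim$reads$id, sim$reads$seq1, sim$reads$qual1,
              p("plate_R1.fastq.gz"))
  write_fastq(sim$reads$id, sim$reads$seq2, sim$reads$qual2,
              p("plate_R2.fastq.gz"))
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("plate_R1.fastq.gz plate_R2.fastq.gz", p("fastq_paths.txt"))
  prim <- sim$scheme$primers
  for (g in c("row", "column")) {
    sel <- prim[prim$group == g, ]
    writeLines(paste(sel$id, sel$full_sequence, sep = "\t"),
               p(sprintf("spacer_barcode_primer_%s.txt",
                         if (g == "row") "FWD" else "REV")))
  }
  bed <- data.frame(chrom = locus$chrom,
                    start = c(locus$start, locus$start + locus$roi$start),
                    end = c(locus$end, locus$start + locus$roi$end),
                    name = c(locus$name, locus$roi$label))
  write.table(bed, p("target_locus.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ref <- Biostrings::DNAStringSet(locus$reference_amplicon)
  names(ref) <- locus$name
  Biostrings::writeXStringSet(ref, p("reference_amplicon.fa"))
  if (!is.null(locus$donor_diffs)) {
    d <- locus$donor_diffs
    writeLines(paste(d$pos + 1L, d$ref, d$alt, sep = "\t"),
               p("donor_diffs.txt"))
  }
  invisible(list(fastq1 = p("plate_R1.fastq.gz"),
                 fastq2 = p("plate_R2.fastq.gz"),
                 truth = p("truth.tsv"),
                 fastq_paths = p("fastq_paths.txt"),
                 fwd_primers = p("spacer_barcode_primer_FWD.txt"),
                 rev_primers = p("spacer_barcode_primer_REV.txt"),
                 bed = p("target_locus.bed"),
                 reference = p("reference_amplicon.fa"),
                 donor = if (!is.null(locus$donor_diffs))
                   p("donor_diffs.txt") else NULL))
}
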