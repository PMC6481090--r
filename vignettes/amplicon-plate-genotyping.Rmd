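---
title: "Genotyping CRISPR-edited clones from dual-barcoded 96-well amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CRISPR-edited clones from dual-barcoded 96-well amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliwell)
```

## The screening problem

CRISPR/Cas editing of a specific base -- for example, switching a GWAS
candidate SNP allele -- relies on homology-directed repair (HDR), which is
far rarer than the competing non-homologous end joining (NHEJ) pathway that
leaves small insertions or deletions (indels) at the cut site. Isolating a
correctly edited clone therefore means screening many single-cell-sorted
clones, typically grown in 96-well plates. Sanger traces are hard to
deconvolute for heterozygous indels; deep sequencing of a short amplicon
over the edit site reads each allele separately and scales to hundreds of
clones per run.

The library design this package analyses amplifies the edited locus with
primers carrying universal m13 linkers, then barcodes every well in a
second PCR round with one of 8 *row* primers and one of 12 *column*
primers. Each barcoding oligo is

```
[3 bp spacer (GAT)] + [8 bp well barcode] + [m13-derived linker]
```

so the final molecule is

```
[GAT + row barcode + row linker] + amplicon + revcomp(GAT + column barcode + column linker)
```

and the 8 x 12 barcode pairs address all 96 wells. Pooled plates are
sequenced as 2 x 250 bp paired-end reads. Because the amplicon is kept to
300--400 bp, the two mates overlap in the middle and the full fragment can
be reconstructed from one read pair ("flashing").

The bundled primer set is derived from the primer files themselves: the
spacer is the longest common prefix over all oligos, each group's linker is
its longest common suffix, and the barcode is the remainder. Nothing is
hard-coded, so schemes with different barcode lengths or linkers load the
same way. (Of note, the row linker embedded in the oligos is a 17 nt
variant of the canonical 16 nt m13fwd sequence; deriving linkers from the
files sidesteps any ambiguity about which to trust.)

## Pipeline stages and their parameters

**Demultiplexing** (`demultiplex_pairs()`). Each mate's fixed-offset
prefix is tested against both primer groups, in both mate-role
orientations, because adaptor ligation is non-directional. A read prefix
matches a primer when the spacer has at most one mismatch, the barcode is
within `max_mismatch` (default 1) of exactly one barcode in the group, and
the first five linker bases have at most one mismatch (a cheap chimera
guard). Two barcodes within tolerance, or a mismatch tie between the two
orientations, leaves the pair unassigned -- we prefer dropping a read to
moving it to the wrong clone. Indels in the prefix are not rescued by a
shifted-window search: the spacer exists precisely to absorb synthesis
edge effects, and a fixed window keeps demultiplexing O(1) per read.
Assigned pairs are trimmed and reoriented so that mate 1 always carries
the row (forward) end; merged fragments then sit on the reference strand.

**Merging** (`merge_pairs()`). The best suffix/prefix overlap between
mate 1 and the reverse-complemented mate 2 is the one minimising the
mismatch ratio over all overlap lengths of at least `min_overlap`
(default 10 nt), ties going to the longer overlap; pairs whose best ratio
exceeds `max_mismatch_ratio` (default 0.25) are reported as unmerged.
These defaults are the de facto standard for short-amplicon overlap
mergers. Only substitutions are considered inside the overlap -- both
mates come from one molecule, so indels between them do not occur. In the
overlap the higher-quality base wins (ties keep mate 1's base) and the
consensus quality is the maximum of the two. Fragments longer than
`2 * read_length - min_overlap` cannot merge and are counted, not
silently dropped.

**Alignment** (`align_semiglobal()`). Merged fragments are aligned to the
reference amplicon with an affine-gap semi-global aligner: the fragment
must align end to end, while unaligned reference overhangs are free, so a
truncated fragment pays no end-gap penalty. Scoring defaults are match
+1, mismatch -2, gap open -5, gap extend -1, with a length-k gap costing
`gap_open + (k-1) * gap_extend`; under these values a 1 bp indel (5) is
cheaper than two substitutions (6), the right prior for Cas9 cut-site
repair. Traceback is deterministic: ties prefer diagonal moves, then
deletions, then insertions, and the leftmost reference end point. When the
fragment has the reference's length and at most one mismatching position
the gap-free diagonal is provably optimal (any gapped or shifted path
forfeits at least a gap penalty), and is returned without running the DP
-- this is what keeps noisy plates fast. Each unique allele is also
aligned as its reverse complement when the forward score is poor, guarding
against swapped primer files. Rather than mapping to a whole genome
build, alignment is against a user-supplied reference amplicon FASTA: for
a 300--400 bp product this loses nothing and removes a multi-gigabyte
dependency.

**Variants and classification** (`extract_variants()`,
`classify_allele()`). Adjacent gap columns of one type become a single
indel, indels are left-aligned against the reference (re-left-aligning is
idempotent), and variants are annotated with the regions of interest they
touch. Classification against the programmed edit is rule-based and
total: no variants is `WT`; variants exactly equal to the donor
substitutions is `HDR`; all donor substitutions plus anything else is
`complex`; otherwise any indel is `NHEJ_indel`, else
`substitution_only`. An allele carrying the donor base *and* an indel is
deliberately `complex`, never `HDR` -- the conservative choice when the
caller's output decides which clones are expanded. How to distinguish
true HDR from PCR or sequencing substitutions is not observable from one
amplicon; the exact-match-to-donor rule is this package's explicit
convention.

**Genotype calling** (`collapse_alleles()`, `call_genotype()`). Identical
fragment sequences are counted as one allele; counts per well are sorted
descending with lexicographic tie-breaks so output is deterministic.
Wells with fewer than `min_reads` merged fragments (default 10, the
screening threshold this protocol operates with) fail as
`failed_low_reads`; the threshold is applied to *merged fragments*
because those are the unit actually genotyped. Alleles below
`min_allele_fraction` (default 0.15) are treated as PCR/sequencing noise;
0.15 suppresses error alleles at realistic depths while keeping all four
alleles of a tetraploid detectable. The top `ploidy` (default 2)
surviving alleles are called. A single surviving allele is reported
`ploidy` times with `homozygote_flag` set -- flagged rather than trusted,
because a large deletion removing one primer site produces exactly the
same signal (the false-homozygote caveat; `validate_amplicon_design()`
warns when no heterozygous SNP is available in the product to control for
this). If more than one but fewer than `ploidy` alleles survive, the
genotype string joins the survivors without padding: inventing copies of
the top allele would overstate certainty. The plate summary reports wells
processed (any input reads), wells successfully sequenced (reported), and
their ratio as a percentage rounded half-away-from-zero to one decimal.

## What the simulator emulates -- and what it does not

`simulate_plate()` generates the full library molecule per well and reads
it exactly as the sequencer would: mate 1 is the first 250 bases of a
uniformly chosen strand, mate 2 the reverse complement of the last 250.
Defaults describe a realistic screening run: log-normal read depth with
median 500 pairs per well (spread 0.6 on the log scale), 3% shallow wells
(Poisson mean 5) and 2% empty wells so threshold behaviour is exercised,
substitution errors i.i.d. at 0.1% per base (the dominant MiSeq error
mode) with errored bases assigned low quality, NHEJ indel sizes geometric
with mean 3 and deletions twice as likely as insertions, and genotype
frequencies in which HDR outcomes are rarer than NHEJ -- published
screens report per-locus success rates but not depth distributions, so
the depth model is a stated assumption, not a measured one. Each
simulated well records its true alleles and genotype in a truth table,
and `write_simulated_plate()` emits the FASTQ pair plus all run metadata
files, so a simulation is a complete pipeline fixture.

Two generator properties are worth knowing. First, a "complex" allele is
built as donor substitutions plus an *insertion*: a deletion could erase
the donor base and silently turn the allele into a plain indel, making
the truth table wrong. Second, the simulator does not model PCR chimeras,
index hopping, indel sequencing errors, coverage bias along the amplicon,
or large deletions extending past the primers. Passing tests on simulated
plates therefore demonstrate that the analysis is correct for the stated
error model, not that every artefact of real libraries is handled; the
false-homozygote caveat in particular is flagged, never resolved, by this
package.

## Numerical and degenerate-input choices

Ambiguity always resolves toward "unassigned"/"failed" rather than a
guess: barcode ties, orientation ties, and overlap ratios above threshold
all drop the read with a recorded reason, and counts reconcile exactly at
every stage (assigned + unassigned = input; merged + unmerged = assigned;
allele counts sum to merged fragments per well). Empty files, empty
wells, and zero-ROI BED files are all legal inputs. A plate with no
processed wells has no defined success rate and errors rather than
reporting 0/0. All coordinates are 0-based half-open internally (BED
convention); 1-based positions appear only in user-facing file formats.
All randomness flows from a single integer seed, and report files contain
no timestamps, so identical inputs reproduce byte-identical outputs.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle written
separately from the implementation: alignment scores against a plain-R
full dynamic program on a thousand random instances up to 12 nt; overlap
detection against an exhaustive offset scan on instances up to 60 nt;
barcode recovery against brute-force Hamming distances over every
single-base mutation of all 20 barcodes; left-alignment against
enumeration of equivalent indel placements. End-to-end, a seeded
zero-error 96-well plate at the default depth model must recover 100% of
truth genotypes, a read-depth sweep of 1--20 error-free reads per well
must locate the reporting boundary exactly at the 10-read threshold, and
ten seeded plates at 0.1% substitution error and 200 reads per well must
genotype at least 95% of wells correctly. These sizes (one plate at
median depth 500, ten plates at depth 200) were chosen as the smallest
runs that exercise the full depth distribution and the noise floor.

## Limitations

Plate-level (i5/i7) demultiplexing is assumed done by the sequencer;
input is one plate's FASTQ pair. Large deletions beyond the amplicon,
off-target edits, and base-editor-specific outcome windows are out of
scope. Zygosity is thresholded, not statistically tested: a well with a
60/40 allele split at depth 20 is called heterozygous without a
confidence measure. The aligner is quadratic in sequence length and
intended for amplicons of a few hundred bases, not long-read products.
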