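---
title: "mirclash: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirclash: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`mirclash` implements two complementary analyses for locating the mRNA
targets of a microRNA from Argonaute-2 (AGO2) immunoprecipitate sequencing:

1. **CLASH chimera calling.** In a CLASH experiment (cross-linking, ligation
   and sequencing of hybrids), a miRNA and the mRNA fragment it is bound to
   inside the RISC complex are ligated into one molecule, so a sequencing
   read can carry both partners. The pipeline reconstructs each insert from
   its overlapping paired-end reads, strips the small-RNA library adapters,
   discards every read explainable as one contiguous reference match, and
   searches the survivors for *partial* local alignments against the mature
   miRNA set and against the transcript set. A read is called chimeric when
   (1) it carries at least one miRNA arm and one mRNA arm and (2) the two
   arms occupy disjoint read intervals.

2. **IP target-site enrichment.** Independently, predicted target sites are
   widened from their 5' end to a 100 nt *extended target region* (TAR)
   inside the transcript's 3'-UTR; the remainder of the UTR is the
   *non-target 3'-UTR* (NT3UTR). For each IP sample the local enrichment of
   a site is

   LE = log2( (TAR/f + c) / (NT3UTR/f + c) )

   with TAR and NT3UTR the read counts overlapping the two regions, `f` the
   sample's relative TMM-effective library size and `c` a pseudocount.
   Sites are ranked by `delta = mean LE(WT) - mean LE(KO)`: a genuine target
   loses AGO2 binding when the miRNA is knocked out, so rank 1 is the
   strongest candidate. Convergence of the two analyses — a site that both
   recruits chimeras and loses IP coverage in the knockout — is the
   pipeline's final read-out (`combined_report`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_overlap` | 30 nt | minimum mate overlap for merging (the upstream merger's `-n 30`; its statistical test is disabled, matching `-p 1.0`) |
| `max_mismatch_rate` (merge) | 0.10 | tolerated mismatch fraction in the chosen overlap; unspecified upstream, chosen to be robust at the simulator's 1% error rate |
| adapters | 3' `TCTGGAATTCTCGGGTGCCAAGGAACTCC`, 5' `GTTCAGAGTTCTACAGTCCGACGATC` | the small-RNA library adapters, stored as DNA (U→T) |
| `word_size` | 7 | exact-word seed for the local aligner (`-W 7`) |
| `evalue_max` | 10 (miRNA), 0.1 (mRNA) | per-class emission thresholds (`-e 10` / `-e 0.1`) |
| match/mismatch, gap open/extend | +2/−3, −5/−2 | classic blastn-style nucleotide scoring; not stated upstream, so documented here and configurable |
| `ka_lambda`, `ka_K` | 0.625, 0.41 | ungapped Karlin–Altschul estimates for +2/−3; E-values are an ordering device, tests rely only on monotonicity |
| `min_arm_len` | 12 nt | suppresses spurious 7-mer "arms" at desk scale |
| `max_gap` | 10 nt | maximum distance between the two arms on the read; 0 reproduces the strictest reading of the non-overlap rule |
| `tar_width` | 100 nt | 5'-extension of each predicted site |
| `pseudocount` | 0.5 | guards the LE log-ratio at zero counts; 0 reproduces the bare formula |
| `m_trim`, `a_trim` | 0.30, 0.05 | TMM trim fractions |
| `le_filter_threshold`, `filter_mode` | 1.0, `wt_min` | site filter before ranking (see below) |

## Design decisions in ambiguous territory

**Direction of the LE filter.** The analysis description compares genotypes
"at each target with local enrichment level < 1", which conflicts with the
stated goal of selecting *enriched* targets: taken literally, it keeps
exactly the sites that show no local pile-up. The default `wt_min` filter
keeps sites with mean WT LE ≥ 1 — a bona fide target is locally enriched in
the WT IP — and a `literal_lt` mode preserves the printed inequality
verbatim. Both are first-class code paths.

**The scale factor `f` is relative.** `f` is the TMM-scaled library size
normalized to geometric mean 1 across samples, not the absolute read count.
Dividing raw counts of tens to hundreds by an absolute library size of tens
of thousands would push every count far below the pseudocount and flatten
the statistic; the relative form keeps counts on their native scale while
still correcting compositional differences between samples. Setting
`factors = 1` disables scaling entirely.

**Counting rules.** A read counts toward a region when it overlaps it by at
least 1 nt; a read overlapping both a TAR and NT3UTR counts toward the TAR
only; a read overlapping two TARs on one transcript (possible when sites
cluster) counts toward the TAR with the larger overlap, ties to the
leftmost. Each read counts at most once per transcript, so per transcript
ΣTAR + NT3UTR counts never exceed the reads placed in its 3'-UTR. No
region-length normalization is applied inside LE (the statistic is a raw
count ratio); a per-kilobase variant can be obtained by scaling the counts
before calling `local_enrichment`.

**One chimera per read.** When several admissible arm pairs exist, the pair
with the highest total alignment score wins (ties: smaller inter-arm gap,
then lexicographic ids), and one call is emitted per read so that
`aggregate_hybrids` never double-counts a molecule. `all_pairs = TRUE`
restores exhaustive emission.

**Contiguity filter in transcript space.** The original genome-plus-
transcriptome mapping filter is collapsed into a transcript-space filter
driven by the same alignment engine in end-to-end mode: a read is removed
when some contiguous reference window explains the whole read at ≤ 6%
mismatches with no indel longer than 2 nt. A 12-mer exact seed pre-selects
candidate windows; a window satisfying the mismatch bound on a ≥ 30 nt read
always contains a long exact run under random substitution errors, so the
seed loses nothing in practice (adversarial error placement could evade it,
as it would for any seeded mapper). The package operates entirely in
transcript coordinates (0-based, half-open); mapping genomic site
predictions onto transcripts is the caller's responsibility.

**Configuration format.** The single-file run configuration is JSON (the
only structured-config parser in the supported dependency set); keys mirror
`pipeline_config()` arguments and command-line flags override scalars.

## The simulated world

The generator states one fixed world rather than a tunable benchmark:

* 5 miRNAs (20–23 nt), 20 transcripts of 200 nt CDS + 400 nt 3'-UTR.
* 5 *true* sites, one per transcript: reverse complement of the owning
  miRNA's 3'-compensatory region (nt 13–19), a 4 nt spacer, the reverse
  complement of the seed (nt 2–8), and a terminal A — the canonical
  seed-plus-compensatory duplex geometry. 15 *decoy* sites are random UTR
  intervals verified to contain no seed complement of any miRNA.
* IP libraries: 20,000 fragments (60–90 nt) per sample, two replicates per
  genotype; placements overlapping a true site's TAR are sampled with
  weight 8 (WT) or 1 (KO). With a 100 nt TAR in a 400 nt UTR and ~75 nt
  fragments this puts a true site's WT LE near +3 and a decoy's near +0.2,
  so the default filter threshold of 1 separates them by design — the
  criterion being tested is whether the *pipeline* preserves that
  separation, not whether the world provides it.
* CLASH libraries: 2,000 read pairs, 20% true hybrids (full or 3'-truncated
  miRNA of ≥ 14 nt ligated to a 25–50 nt site-covering UTR fragment, in
  random orientation), 80% background (contiguous UTR or miRNA fragments),
  all flanked by the two library adapters, 1% per-base substitution error
  per mate, 101 bp paired-end reads.

**Junction-unambiguous hybrids.** When the transcript base immediately
upstream of the ligated fragment happens to match the read base at the end
of the miRNA arm, the mRNA arm's optimal local alignment extends across the
junction and the two arms overlap by 1–2 nt on the read; the verbatim
non-overlap rule then rejects the read no matter how well the caller works
(with random junctions this affects roughly a quarter of hybrids — a real
loss mode of this class of pipeline). Because the recovery criteria are
meant to measure pipeline correctness rather than this inherent ambiguity,
the generator resamples any hybrid for which an anchored affine-gap
extension across either junction scores ≥ 0. Real libraries contain
junction-ambiguous chimeras; recovery rates on real data will be lower than
the synthetic figures for exactly this reason.

**What a green test does not establish.** The simulator uses substitution
errors only (no indels — indel robustness is exercised by aligner unit
tests), uniform fragment sampling, constant quality strings, no
PCR duplicates and no cross-link-induced deletions. Recovery and ranking
results on this world validate the algorithmic contracts, not performance
on real libraries.

## Numerical notes

* All internal coordinates are 0-based half-open; the blast-style hit table
  is 1-based inclusive with subject start > end on the minus strand,
  converted only at that boundary.
* `N` never matches: it is excluded from seeds and scores as a mismatch.
* TMM reference sample: the one whose upper-quartile/library-size ratio is
  closest to the mean such ratio; gene weights are the standard delta-method
  inverse variances; factors are reported with geometric mean 1. Ties in
  the M or A trim are broken in stable input order; since tied genes carry
  identical values and weights, the trimmed mean is unaffected.
* The merger scans every overlap length from `min_overlap` to the shorter
  mate length and keeps the fewest-mismatch overlap, largest on ties; at
  mismatching consensus positions the higher-quality base wins, read 1 on
  ties or when qualities are absent.
* Adapter trimming happens after merging (the order is not documented
  upstream; trimming first would truncate the very overlap the merger
  needs). Trimming requires ≥ 8 matching bases, longest match wins; matches
  of ≥ 10 nt tolerate 10% mismatches (`max_error_rate`), because a
  sequencing error inside an adapter would otherwise leave the whole
  adapter untrimmed, and such residues measurably seed spurious miRNA arms
  next to genuine mRNA arms — the dominant false-chimera mode at a 1% error
  rate. `max_error_rate = 0` restores strictly exact matching. Merged reads
  shorter than 18 nt after trimming are dropped.

## Known limitations

* E-values are calibrated only up to the ungapped Karlin–Altschul
  approximation; they order hits correctly but are not comparable to an
  external aligner's values.
* One best local alignment is reported per (read, subject, strand); a read
  ligating two fragments of the *same* transcript is therefore summarized
  by its best mRNA arm only.
* Genome coordinates, gene-level differential expression and
  hybridization-energy annotation are out of scope.
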