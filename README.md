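# mirclash

Target discovery for a microRNA from AGO2 immunoprecipitate sequencing, in
two convergent ways:

* **CLASH chimera calling** — in a CLASH library (cross-linking, ligation
  and sequencing of hybrids), a miRNA and the mRNA fragment it binds inside
  the RISC complex are ligated into one molecule. `mirclash` merges each
  overlapping read pair into one insert, trims the small-RNA library
  adapters, removes every read explainable as a single contiguous reference
  match, finds partial local alignments ("arms") against the mature-miRNA
  and transcript references with a seeded affine-gap aligner, and calls a
  read chimeric when it carries one miRNA arm and one mRNA arm on disjoint
  read intervals.

* **IP target-site enrichment** — each predicted target site is widened
  from its 5' end to a 100 nt extended target region (TAR) within the
  transcript's 3'-UTR; the rest of the UTR is the non-target region
  (NT3UTR). Per sample,

  `LE = log2( (TAR/f + c) / (NT3UTR/f + c) )`

  where TAR/NT3UTR are overlapping read counts, `f` the sample's relative
  TMM-effective library size and `c = 0.5` a pseudocount. Sites passing the
  filter (mean wild-type LE ≥ 1 by default) are ranked by
  `delta = mean LE(WT IP) − mean LE(KO IP)`; rank 1 is the site that loses
  the most AGO2 binding when the miRNA is knocked out.

A synthetic-data module generates references with planted seed-matched
target sites, WT/KO IP libraries with genotype-dependent TAR pile-up, and
adapter-flanked CLASH hybrids with per-read ground truth, so every stage is
testable against known answers. See `vignettes/mirclash-methods.Rmd` for
the model, parameter rationale and the simulator's stated world.

## Worked example

Simulate a small study (5 true sites among 20, 400 CLASH pairs, 4 IP
samples of 5,000 reads) and run everything:

```r
library(mirclash)
cfg_path <- simulate_to_dir(
  sim_config(seed = 42, n_clash_reads = 400, n_ip_reads_per_sample = 5000),
  "demo")
status <- mirclash_cli(c("run", "--config", cfg_path))
rep <- read_enrichment_table("demo/results/combined_report.tsv")
```

The stage log shows the read funnel
(`pairs 400 -> merged 400 -> trimmed 400 -> non-contiguous 86`) and the
combined report converges on the five planted sites:

```
  site_id transcript_id le_wt   le_ko delta rank chimera_support chimera_mirnas
1 site_03         TX007  3.10 -0.1058  3.21    1              18         miR-03
2 site_01         TX001  1.96 -1.0801  3.04    2              10         miR-01
3 site_02         TX008  2.40 -0.5991  3.00    3              14         miR-02
4 site_04         TX014  2.49 -0.4242  2.91    4              20         miR-04
5 site_05         TX013  2.97  0.0833  2.88    5              16         miR-05
```

Each true site is locally enriched in the WT IP (`le_wt` ≈ 2–3, i.e. its
TAR catches 4–8× more reads than its size alone would predict), loses that
enrichment in the knockout (`le_ko` ≈ 0), and is independently supported by
10–20 CLASH chimeras that ligate the correct miRNA to that transcript
(`hybrids_by_pair.tsv` tabulates the same calls per (miRNA, transcript)
pair). The 15 decoy sites fall below the `le_wt ≥ 1` filter and are absent
from the ranking.

Every run writes a `manifest.json` (configuration hash, seed, stage counts,
output checksums); rerunning the same configuration reproduces every output
byte for byte.

## Command line

```
mirclash simulate --config sim.json --out dir     # write a synthetic study
mirclash run --config pipeline.json               # full pipeline
mirclash prep|align|chimera|enrich|report ...     # individual stages
```

(`inst/exec/mirclash` is the `Rscript` wrapper; exit codes: 0 success,
2 validation/usage error, 3 stage failure.)

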