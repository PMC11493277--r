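# nascentr

Analysis of nascent-transcription sequencing (mNET-seq) and companion
RNA-seq data at single-nucleotide resolution, for researchers studying how
transcription, pre-mRNA splicing and termination interact — e.g. what a
putative splicing inhibitor does to RNA polymerase II before and after it
affects splicing.

mNET-seq captures the RNA still held by elongating pol II; the 3′ end of
the protected fragment marks the polymerase's genomic position exactly.
`nascentr` turns coordinate-sorted paired-end alignments into:

* **single-nucleotide polymerase tags** — from each properly paired
  alignment (`-f 3`), the reference coordinate of mate 2's 3′-terminal
  aligned base (CIGAR-walked over M/D/N/=/X), stranded by mate 1's
  orientation (with a `flip_strand` switch for the opposite chemistry);
* **strand-specific coverage**, raw or RPKM
  (`count / (bin_kb × library_millions)`), written as bedGraph;
* **per-gene splicing efficiency** `SE = spliced / (spliced + unspliced)`,
  where a read is spliced iff its CIGAR contains an N operation and reads
  are assigned to genes split-aware (aligned blocks only) and
  strand-aware, compared across conditions with Wilcoxon rank-sum /
  signed-rank tests;
* **gene classes** — most-expressed isoform per gene, a strict
  "more than 10 reads in 2 replicates" expression filter, and
  intron-containing / intronless / histone labels with the
  longest-intronless-gene length cap;
* **scaled metagene profiles** (unscaled 10 bp flanks, length-weighted
  body rescaling) and a **readthrough index** (mean signal downstream of
  the poly(A) site over mean body signal) that quantifies termination
  defects;
* **bench-assay arithmetic** — ChIP %input with IgG background removal,
  ΔΔCt relative expression, western-blot normalisation ratios, RT-PCR
  percent-unspliced, and two-fold / adjusted-p < 0.05 DE calls.

A fully parameterised synthetic-data generator (gene classes with
realistic lengths, promoter-proximal pause peak, uniform body signal,
exponential post-poly(A) readthrough, per-gene intron retention, 35–100 nt
paired inserts) makes every stage testable end to end with known truth.
See `vignettes/nascentr-methods.Rmd` for the models and defaults.

## Worked example

Simulate a small two-condition experiment (control vs a treatment that
halves pausing, lowers body density to 60 % and triples post-poly(A)
readthrough), then run the full analysis:

```r
library(nascentr)

cfg <- sim_config(seed = 5,
                  n_genes = c(intron_containing = 20, intronless = 5, histone = 2),
                  depth = 20000)
sim_dir <- file.path(tempdir(), "demo")
run_simulate(cfg, sim_dir)           # annotation.gtf, rnaseq.sam, netseq_*.sam, truth.json
s <- run_analysis(sim_dir)           # bedGraphs, TSV tables, summary.json

s$class_mean_efficiency
#> # A tibble: 3 × 3
#>   class             mean_efficiency     n
#>   <chr>                       <dbl> <int>
#> 1 histone                     0         2
#> 2 intron_containing           0.850    20
#> 3 intronless                  0         5

unlist(s$readthrough_median)
#>   control   treated
#> 0.6037953 1.8510071

signif(s$readthrough_rank_sum_p, 3)
#> [1] 1.03e-15
```

Reading the numbers: intron-containing genes show a mean splicing
efficiency of 0.85 — the generator's intron-retention probability is
0.15, and `1 − SE` recovers it — while single-exon genes have no spliced
reads by construction. The per-gene readthrough index (signal in the 2 kb
past the poly(A) site over body signal) triples under treatment (median
1.85 vs 0.60), and the rank-sum test across genes calls that termination
defect highly significant. The per-gene tables
(`splicing_efficiency.tsv`, `readthrough_index.tsv`), metagene profiles
(`profile_*.tsv`) and strand-specific bedGraphs are written next to the
inputs, with parameters recorded in `summary.json`.

Individual steps compose with pipes, e.g.:

```r
read_alignment_pairs(file.path(sim_dir, "netseq_control.sam")) |>
  filter_proper_pairs() |>
  tags_from_pairs(flip_strand = TRUE) |>
  tags_to_coverage(read_chrom_sizes(file.path(sim_dir, "netseq_control.sam")),
                   normalize = "RPKM")
```

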