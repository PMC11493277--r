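---
title: "Models and methods behind nascentr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nascentr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentr)
```

# What the package computes

mNET-seq immunoprecipitates RNA polymerase II together with the nascent RNA
held in its active site; after MNase digestion and size selection of
35–100 nt fragments, the 3′-OH of the protected RNA marks the position of
the polymerase at single-nucleotide resolution. `nascentr` implements the
computational half of that assay and its companion RNA-seq splicing
analysis:

1. **Tag extraction.** From each properly paired alignment (both mates
   mapped, proper-pair flag set — the `-f 3` filter), the polymerase
   position is the reference coordinate of mate 2's 3′-terminal *aligned*
   base: for a forward mate 2, the leftmost position plus the summed
   reference-consuming CIGAR widths (M, D, N, `=`, X) minus one; for a
   reverse mate 2, its leftmost aligned base. The tag strand is mate 1's
   orientation, optionally inverted (`flip_strand`).
2. **Coverage.** Tags are binned per strand (default 1 bp bins) and
   optionally RPKM-normalised:
   $\mathrm{RPKM} = \dfrac{\text{count}}{\text{bin length (kb)}\times\text{library size (millions)}}$.
3. **Splicing efficiency.** Every read (each mate independently) is
   *spliced* iff its CIGAR contains an N operation. For a gene $g$,
   $\mathrm{SE}_g = \dfrac{\#\text{spliced}}{\#\text{spliced}+\#\text{unspliced}}$
   over reads whose aligned blocks (split-aware: N gaps excluded) overlap
   the gene by at least one base on the matching strand. Conditions are
   compared with Wilcoxon rank-sum (unpaired) or signed-rank (paired)
   tests.
4. **Metagene profiles.** Scaled-gene matrices with unscaled flanks at
   10 bp bins and a body resampled to a fixed bin count by length-weighted
   averaging; profiles are column means over regions, then over
   replicates.
5. **Readthrough index.** Mean signal in a window downstream of the
   poly(A) site divided by mean gene-body signal — a per-gene summary of a
   transcription termination defect.
6. **Bench-assay arithmetic.** ChIP %input with IgG background removal and
   input-dilution correction, ΔΔCt relative expression, the western-blot
   double ratio, the RT-PCR percent-unspliced formula, and the
   two-fold/adjusted-p differential-expression call.

# The synthetic-data generator

Every stage is exercised end to end on simulated data with known truth;
no external downloads are needed.

## Gene models

Three transcription-unit classes are drawn with class-specific length
ranges and packed without overlap onto two synthetic chromosomes, using
both strands and uniform intergenic gaps (2–8 kb) plus a readthrough
margin at the chromosome ends:

| parameter | default | rationale |
|---|---|---|
| class counts | 2,236 / 193 / 40 (intron-containing / intronless / histone) | the analyzed HeLa gene set sizes |
| intronless length | 0.5–10 kb | intronless mRNAs are short; the longest defines the length cap |
| histone length | 0.4–1 kb | replication-dependent histone genes are compact |
| intron-containing length | 1–10 kb, capped at the longest intronless gene | the class-comparison cap is then exercised non-trivially |
| exons per intron-containing gene | 3–12 | typical short-gene exon counts |

Intronless and histone genes have exactly one exon. Exon/intron partitions
are random with a 30 bp minimum segment.

## Polymerase occupancy

Per-base tag weight along a gene of length $L$ at distance $d$ from the
TSS:

$$
w(d) \;=\;
\begin{cases}
1 + h\,e^{-d^2/2\sigma^2} & 0 \le d < L \quad\text{(body + pause peak)}\\[2pt]
\gamma\, e^{-(d-L)/\tau} & L \le d < L + E \quad\text{(readthrough tail)}
\end{cases}
$$

in units of the body density (default 10 tags/kb, which sets the relative
sequencing mass of genes). Defaults: pause height $h = 10$ and width
$\sigma = 150$ bp (promoter-proximal pausing is typically a 5–50-fold
enrichment over the body within ~150 bp of the TSS), tail extent
$E = 5$ kb with length constant $\tau = 2$ kb, and gain $\gamma = 1$ for
control libraries. A "termination-defect" condition multiplies the tail
by `readthrough_gain` (default 3) and, in the pipeline, scales pausing by
0.5 and body density by 0.6 — a treatment that downregulates
transcription while delaying termination. Total depth is fixed per
library, so condition contrasts are read off RPKM-normalised tracks
exactly as they would be from real libraries sequenced to similar depth.

## Read emission and library chemistry

Insert sizes are uniform on 35–100 nt (the gel size selection), reads are
100 nt, and inserts shorter than the read are soft-clipped so every mate's
CIGAR consumes exactly `read_length` query bases. Nascent RNA cannot start
upstream of the TSS, so fragments for positions within the pause peak are
shortened accordingly.

The emitted chemistry makes mate 2 the sense read covering the whole
insert — its 3′-terminal aligned base *is* the polymerase position — and
mate 1 the antisense read. This is the only geometry in which a
convergent, properly paired 35–100 nt fragment fully covered by the read
places the polymerase position on mate 2's aligned 3′ end. Its corollary
is that mate 1's orientation is the reverse of the transcript strand, so
the pipeline extracts tags with `flip_strand = TRUE`; the extraction rule
itself defaults to the unflipped convention and the flag covers either
chemistry. mNET-seq fragments are emitted as single-block genomic
intervals: 35–100 nt nascent 3′-end fragments rarely span a splice
junction, so spliced nascent CIGARs are not modelled.

RNA-seq fragments (for the splicing module) are anchored on a randomly
chosen internal junction. With per-gene probability $\theta$
(`intron_retention`, default 0.15 — chromatin-associated RNA retains a
minority of introns at steady state) the fragment is emitted
intron-retaining as a contiguous pre-mRNA interval; otherwise it is
spliced, with mates carrying N operations over the intron. Placement
guarantees both mates cross the anchor junction with ≥ 8 aligned bases on
each side (the usual junction-overhang requirement), so each read's CIGAR
class reflects the fragment's retention status and
$1-\mathrm{SE}_g$ is a binomial estimate of $\theta_g$ at the emitted
junction depth. Fragments are 130–180 nt so that two 100 nt mates can
both span the junction.

## What the generator does not emulate

Base composition (sequences are uniform placeholders), sequencing errors
and quality variation, PCR duplicates, multimapping, overlapping or
nested genes, expression-level variation between genes of a class beyond
gene length, MNase digestion bias, and alternative isoforms (one
transcript per gene). Passing tests therefore demonstrate the
correctness of the *computations* under the stated statistical model, not
robustness to alignment artefacts in real libraries.

# Statistical and numerical choices

* **Rank tests.** `stats::wilcox.test` with the exact null when both
  sample sizes are ≤ 25 (and no ties force an approximation), otherwise
  the normal approximation with continuity correction; two-sided
  throughout. Paired comparisons drop zero differences before ranking;
  when *every* difference is zero the test degenerates and p = 1 is
  returned explicitly (the underlying routine would otherwise error on an
  empty vector).
* **Null calibration.** The type-I-error check draws per-gene
  spliced/unspliced counts from the generator's own junction law
  (binomial at fixed depth, default 50 reads/gene) rather than re-emitting
  SAM records each replication; the law is shared code with the read
  simulator.
* **Efficiency floor.** Genes with fewer than 10 counted reads are
  flagged `low_coverage` (ratio instability) but never silently removed.
* **Expression filter.** Strictly more than `min_reads` (default 10) in
  at least `min_replicates` (default 2) replicates; boundary counts of
  exactly 10 fail.
* **Isoform ties.** The lexicographically smallest `transcript_id` wins
  and the gene is flagged — deterministic and auditable.
* **Gene size for the length cap** is the genomic span of the selected
  isoform (TSS to poly(A) site), not the mature mRNA length: metagene and
  length comparisons are genomic.
* **Histone identity** comes from a user-supplied id list, never from
  gene-symbol parsing.
* **Body resampling** works on the cumulative integral of the source bins
  with linear interpolation at fractional cut points: a 2-bin body
  `[2, 4]` resampled to 3 bins gives `[2, 3, 4]` (overlap weights 1,
  ½ + ½, 1), constants are preserved exactly, and the length-weighted
  mean of the output equals the mean raw signal over the body.
* **Chromosome edges.** Truncated flanks are zero-filled (keeping
  matrices rectangular) and flagged per region.
* **Readthrough index windows.** Default 2 kb downstream window and
  500 bp TSS-side body exclusion (skipping the pause peak); for genes
  shorter than twice the exclusion (histone genes), the exclusion shrinks
  to half the gene so the body window is never empty.
* **ChIP background.** IgG-subtracted signal is clamped at zero —
  %input is a proportion — and clamped rows are flagged. The
  conventional readings of the ChIP and qPCR normalisations
  (dilution-corrected %input; ΔΔCt with efficiency 2) are used, with
  every constant overridable.
* **Coordinates.** 0-based half-open everywhere internally; SAM/GTF
  (1-based inclusive) and BED/bedGraph (0-based half-open) convert only
  at the I/O boundary.
* **Reproducibility.** Each generator operation draws from its own RNG
  stream derived from `seed` plus a fixed per-operation offset, so adding
  a simulation stage never perturbs the others; fixed seeds give
  byte-identical files.

# Problem sizes used by the tests

The shipped tests and the acceptance script run on deliberately small
instances chosen once as representative: 1–20 genes per class for unit
checks; retention recovery at $\theta \in \{0.05, 0.3, 0.8\}$ with 10,000
junction fragments per gene; null calibration with 200 genes per arm, 50
reads per gene and 1,000 replications; and shape recovery on 150
intron-containing (plus 30 intronless and 8 histone) genes at $10^5$
pairs per condition. These sizes give the binomial standard errors the
assertions quote while keeping a full run in minutes on one core.

# Known limitations

* Single-isoform genes only; isoform selection logic is exercised through
  hand-built count tables rather than multi-isoform simulation.
* The readthrough tail is a single exponential; real termination zones
  mix cleavage-site readthrough with pausing downstream of the poly(A)
  site.
* Histone genes are modelled with the same tail form as poly(A) genes
  (their own gain), without stem-loop/cleavage-site mechanics.
* When an insert exceeds the read length, the extracted 3′ end lies
  upstream of the true polymerase position — an inherent limitation of
  the assay that the default 35–100 nt inserts with 100 nt reads avoid.
* Efficiency is gene-level, read-based; per-intron PSI or junction-level
  quantification is out of scope.
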