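# CIGAR-based splicing efficiency and condition comparisons.

#' Classify a read as spliced or unspliced from its CIGAR
#'
#' A read is spliced iff its CIGAR contains at least one `N`
#' (reference-skipping) operation; insertions, deletions and clips do not
#' count. Vectorised.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Character vector, `"spliced"` or `"unspliced"`.
#' @examples
#' classify_read(c("36M", "20M1000N16M", "10M2I24M"))
#' @export
classify_read <- function(cigar) {
  assert_valid_cigar(cigar)
  ifelse(grepl("N", cigar, fixed = TRUE), "spliced", "unspliced")
}

pairs_to_reads <- function(pairs) {
  bind_rows(
    tibble(pair_id = pairs$pair_id, mate = 1L, chrom = pairs$chrom,
           start = pairs$start1, cigar = pairs$cigar1,
           strand = pairs$strand1, pair_strand = pairs$strand1),
    tibble(pair_id = pairs$pair_id, mate = 2L, chrom = pairs$chrom,
           start = pairs$start2, cigar = pairs$cigar2,
           strand = pairs$strand2, pair_strand = pairs$strand1))
}

#' Per-gene splicing efficiency from aligned read pairs
#'
#' Each mate is counted independently (read-level counting). A read counts
#' for a gene iff its aligned blocks (CIGAR M/=/X segments -- N gaps are
#' excluded, i.e. counting is split-aware) overlap the gene span by at
#' least one base and, when `stranded`, the pair's assigned strand (mate
#' 1's orientation) matches the gene strand. Reads are partitioned by
#' [classify_read()] and efficiency is `spliced / (spliced + unspliced)`,
#' undefined (`NA`) when no read overlaps the gene.
#'
#' @param pairs Pairs tibble of RNA-seq alignments.
#' @param genes A `gene_annotation` or genes tibble (`gene_id`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param stranded Require strand agreement between read pair and gene.
#' @param min_reads Genes with fewer counted reads than this are flagged
#'   `low_coverage` (ratio instability), not removed.
#' @return Tibble `gene_id`, `spliced`, `unspliced`, `efficiency`,
#'   `low_coverage`.
#' @export
gene_splicing_efficiency <- function(pairs, genes, stranded = TRUE,
                                     min_reads = 10L) {
  g <- if (inherits(genes, "gene_annotation")) genes$genes else as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(g)))
  if (any(g$end <= g$start)) {
    abort(paste0("Zero- or negative-length gene(s): ",
                 paste(utils::head(g$gene_id[g$end <= g$start], 5L),
                       collapse = ", ")))
  }
  base <- tibble(gene_id = g$gene_id, spliced = 0L, unspliced = 0L)
  if (nrow(pairs) > 0L) {
    reads <- pairs_to_reads(filter_proper_pairs(pairs))
    reads$splice_class <- classify_read(reads$cigar)
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      reads$cigar, pos = reads$start + 1L, ops = c("M", "=", "X"),
      reduce.ranges = TRUE)
    nb <- S4Vectors::elementNROWS(blocks)
    block_gr <- GenomicRanges::GRanges(
      seqnames = rep(reads$chrom, nb),
      ranges = unlist(blocks, use.names = FALSE),
      strand = rep(reads$pair_strand, nb))
    gene_gr <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    hits <- GenomicRanges::findOverlaps(block_gr, gene_gr,
                                        ignore.strand = !stranded)
    hit_tab <- distinct(tibble(
      read = rep(seq_len(nrow(reads)), nb)[S4Vectors::queryHits(hits)],
      gene = S4Vectors::subjectHits(hits)))
    counted <- tibble(gene_id = g$gene_id[hit_tab$gene],
                      splice_class = reads$splice_class[hit_tab$read]) |>
      dplyr::count(.data$gene_id, .data$splice_class) |>
      tidyr::pivot_wider(names_from = "splice_class", values_from = "n",
                         values_fill = 0L)
    for (col in c("spliced", "unspliced")) {
      if (!col %in% names(counted)) counted[[col]] <- 0L
    }
    base <- bind_rows(counted[c("gene_id", "spliced", "unspliced")],
                      base[!base$gene_id %in% counted$gene_id, ])
  }
  base |>
    mutate(total = .data$spliced + .data$unspliced,
           efficiency = ifelse(.data$total > 0,
                               .data$spliced / .data$total, NA_real_),
           low_coverage = .data$total < min_reads) |>
    select("gene_id", "spliced", "unspliced", "efficiency", "low_coverage") |>
    arrange(.data$gene_id)
}

#' Compare splicing efficiency between two conditions
#'
#' Unpaired comparisons use the Wilcoxon rank-sum test on the two
#' efficiency vectors; paired comparisons use the Wilcoxon signed-rank test
#' on per-gene differences, with zero differences dropped before ranking
#' (if every difference is zero the test degenerates to p = 1). Exact null
#' distributions are used when both sample sizes are at most 25 (and no
#' ties force an approximation); otherwise the normal approximation with
#' continuity correction. Two-sided throughout.
#'
#' @param records_a,records_b Splicing-record tibbles (from
#'   [gene_splicing_efficiency()]) or bare numeric efficiency vectors.
#'   Paired comparisons match records by `gene_id` when available.
#' @param paired Use the signed-rank test on per-gene differences.
#' @param exact_max Largest sample size for which the exact null is used.
#' @return A one-row tibble of class `splicing_test`: `method`,
#'   `statistic`, `p_value`, `n_a`, `n_b`, `n_used`.
#' @export
compare_splicing <- function(records_a, records_b, paired = FALSE,
                             exact_max = 25L) {
  eff <- function(x) {
    if (is.numeric(x)) return(x)
    stopifnot(is.data.frame(x), "efficiency" %in% names(x))
    x$efficiency
  }
  if (paired && is.data.frame(records_a) && is.data.frame(records_b) &&
      all(c("gene_id") %in% names(records_a)) &&
      all(c("gene_id") %in% names(records_b))) {
    m <- dplyr::inner_join(
      select(records_a, "gene_id", eff_a = "efficiency"),
      select(records_b, "gene_id", eff_b = "efficiency"), by = "gene_id")
    a <- m$eff_a; b <- m$eff_b
  } else {
    a <- eff(records_a); b <- eff(records_b)
  }
  keep <- if (paired) !is.na(a) & !is.na(b) else NULL
  if (paired) { a <- a[keep]; b <- b[keep] } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (paired && length(a) < 2L) abort("Fewer than 2 usable genes for a paired test.")
  if (!paired && (length(a) < 2L || length(b) < 2L)) {
    abort("Fewer than 2 usable genes in one of the arms.")
  }

  if (paired) {
    d <- a - b
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      res <- tibble(method = "Wilcoxon signed-rank", statistic = 0,
                    p_value = 1, n_a = length(a), n_b = length(b),
                    n_used = 0L)
      return(structure(res, class = c("splicing_test", class(res))))
    }
    ht <- suppressWarnings(wilcox.test(
      nz, exact = length(nz) <= exact_max, correct = TRUE))
    res <- tibble(method = "Wilcoxon signed-rank",
                  statistic = unname(ht$statistic), p_value = ht$p.value,
                  n_a = length(a), n_b = length(b), n_used = length(nz))
  } else {
    ht <- suppressWarnings(wilcox.test(
      a, b, exact = length(a) <= exact_max && length(b) <= exact_max,
      correct = TRUE))
    res <- tibble(method = "Wilcoxon rank-sum",
                  statistic = unname(ht$statistic), p_value = ht$p.value,
                  n_a = length(a), n_b = length(b),
                  n_used = length(a) + length(b))
  }
  structure(res, class = c("splicing_test", class(res)))
}

#' @export
tidy.splicing_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p_value)
}

#' @export
glance.splicing_test <- function(x, ...) {
  tibble(p.value = x$p_value, n_a = x$n_a, n_b = x$n_b, n_used = x$n_used)
}

# Per-gene spliced/unspliced junction counts under retention probability
# `theta` at a fixed junction depth. This is the generator's per-gene law
# for junction fragments; the read simulator and the null-calibration
# routine share it.
draw_junction_counts <- function(n_genes, theta, depth) {
  unspliced <- rbinom(n_genes, depth, theta)
  tibble(gene_id = sprintf("G%05d", seq_len(n_genes)),
         spliced = depth - unspliced, unspliced = unspliced,
         efficiency = (depth - unspliced) / depth)
}

#' Type-I error of the splicing comparison under the generator's null
#'
#' Repeatedly draws two arms of per-gene splicing efficiencies from the
#' same junction-count law (identical retention probability, identical
#' depth: a true null), runs [compare_splicing()] on each replication and
#' reports the rejection rate at level `alpha`. A calibrated test should
#' reject close to `alpha`.
#'
#' @param n_genes Genes per arm.
#' @param theta Common intron-retention probability.
#' @param depth Junction reads per gene.
#' @param n_reps Number of null replications.
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @return A list with `rejection_rate`, `n_reps` and the vector of
#'   p-values.
#' @export
splicing_null_calibration <- function(n_genes = 200L, theta = 0.3,
                                      depth = 50L, n_reps = 1000L,
                                      alpha = 0.05, seed = 1L) {
  p <- withr::with_seed(seed, vapply(seq_len(n_reps), function(i) {
    a <- draw_junction_counts(n_genes, theta, depth)$efficiency
    b <- draw_junction_counts(n_genes, theta, depth)$efficiency
    compare_splicing(a, b)$p_value
  }, numeric(1)))
  list(rejection_rate = mean(p < alpha), n_reps = n_reps, p_values = p)
}

#' Percentage of unspliced RNA from gel densitometry
#'
#' `100 * unspliced / (spliced + unspliced)`, the RT-PCR band
#' quantification of intron retention.
#'
#' @param data Tibble with `spliced_signal` and `unspliced_signal` columns
#'   (arbitrary but common densitometry units, non-negative).
#' @return The tibble with a `percent_unspliced` column appended.
#' @examples
#' percent_unspliced(tibble::tibble(spliced_signal = 75, unspliced_signal = 25))
#' @export
percent_unspliced <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("spliced_signal", "unspliced_signal") %in% names(data)))
  s <- data$spliced_signal; u <- data$unspliced_signal
  if (any(s < 0 | u < 0)) abort("Densitometry signals must be non-negative.")
  if (any(s + u == 0)) abort("spliced + unspliced signal must be positive.")
  mutate(data, percent_unspliced = 100 * u / (s + u))
}
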