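# CIGAR splice classification, per-gene efficiency, condition comparisons.

test_that("reads are spliced iff the CIGAR holds an N operation", {
  expect_equal(classify_read(c("36M", "20M1000N16M", "10M2I24M")),
               c("unspliced", "spliced", "unspliced"))
  expect_error(classify_read("36Q"), "Malformed")
})

test_that("toy region efficiency matches brute-force overlap enumeration", {
  gene <- tibble::tibble(gene_id = "G", chrom = "c", strand = "+",
                         start = 1000L, end = 2000L)
  pairs <- dplyr::bind_rows(
    # both mates spliced
    toy_pair("s1", chrom = "c", start1 = 1100L, cigar1 = "10M200N26M",
             start2 = 1600L, cigar2 = "18M50N18M", strand2 = "-"),
    # mate 1 spliced, mate 2 unspliced: mates count independently
    toy_pair("s2", chrom = "c", start1 = 1200L, cigar1 = "20M100N16M",
             start2 = 1700L, cigar2 = "36M", strand2 = "-"),
    # pair on the wrong strand: ignored when stranded
    toy_pair("w1", chrom = "c", start1 = 1300L, cigar1 = "36M", strand1 = "-",
             start2 = 1700L, cigar2 = "36M", strand2 = "+"),
    # pair outside the gene
    toy_pair("o1", chrom = "c", start1 = 5000L, cigar1 = "36M",
             start2 = 5400L, cigar2 = "36M", strand2 = "-"))
  rec <- gene_splicing_efficiency(pairs, gene, stranded = TRUE)
  # brute-force enumeration: reads s1.1, s1.2, s2.1 spliced; s2.2 unspliced
  expect_equal(rec$spliced, 3L)
  expect_equal(rec$unspliced, 1L)
  expect_equal(rec$efficiency, 0.75)
  expect_true(rec$low_coverage)
  unstr <- gene_splicing_efficiency(pairs, gene, stranded = FALSE)
  expect_equal(unstr$spliced + unstr$unspliced, 6L)
})

test_that("a read overlapping only through its N gap is not counted", {
  gene <- tibble::tibble(gene_id = "G", chrom = "c", strand = "+",
                         start = 1000L, end = 1100L)
  gap_read <- toy_pair("g1", chrom = "c",
                       start1 = 900L, cigar1 = "36M", strand1 = "+",
                       start2 = 950L, cigar2 = "10M300N26M", strand2 = "-")
  # mate1 [900,936) misses; mate2 blocks [950,960) and [1260,1286) miss,
  # but mate2's N gap [960,1260) spans the gene
  rec <- gene_splicing_efficiency(list(gap_read)[[1]], gene)
  expect_equal(rec$spliced + rec$unspliced, 0L)
  expect_true(is.na(rec$efficiency))
})

test_that("zero-length genes are rejected", {
  gene <- tibble::tibble(gene_id = "G", chrom = "c", strand = "+",
                         start = 10L, end = 10L)
  expect_error(gene_splicing_efficiency(toy_pair(), gene), "length gene")
})

test_that("rank-sum example reproduces the exact enumeration p-value", {
  res <- compare_splicing(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(res$p_value, 0.1)   # 2 / choose(6, 3) enumerated
  expect_s3_class(res, "splicing_test")
  expect_equal(tidy(res)$p.value, 0.1)
})

test_that("identical paired records give p = 1 with zero differences dropped", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      efficiency = c(0.2, 0.5, 0.9))
  res <- compare_splicing(a, a, paired = TRUE)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_used, 0L)
})

test_that("comparisons with fewer than two usable genes error", {
  expect_error(compare_splicing(c(0.1), c(0.5, 0.6)), "Fewer than 2")
  a <- tibble::tibble(gene_id = "g1", efficiency = 0.2)
  expect_error(compare_splicing(a, a, paired = TRUE), "Fewer than 2")
})

test_that("measured efficiency recovers theta and is monotone in theta", {
  one_gene_cfg <- function(theta, seed) {
    sim_config(seed = seed, n_genes = c(intron_containing = 1L,
                                        intronless = 0L, histone = 0L),
               intron_retention = theta)
  }
  eff_at <- function(theta, depth = 2000) {
    cfg <- one_gene_cfg(theta, seed = 13)    # common random numbers
    s <- simulate_annotation(cfg)
    r <- simulate_rnaseq_pairs(s$annotation, s$truth, cfg, depth = depth)
    gene_splicing_efficiency(r$pairs, s$annotation)$efficiency
  }
  thetas <- c(0.1, 0.4, 0.7)
  effs <- vapply(thetas, eff_at, numeric(1))
  for (i in seq_along(thetas)) {
    se3 <- 3 * sqrt(thetas[i] * (1 - thetas[i]) / 2000)
    expect_lt(abs((1 - effs[i]) - thetas[i]), se3)
  }
  expect_true(all(diff(effs) < 0))           # higher retention, lower efficiency
})

test_that("splice classification partitions every counted read", {
  cfg <- small_config(seed = 19)
  s <- simulate_annotation(cfg)
  r <- simulate_rnaseq_pairs(s$annotation, s$truth, cfg, depth = 600)
  rec <- gene_splicing_efficiency(r$pairs, s$annotation)
  # every emitted read lies in its gene, and both mates are counted
  expect_equal(sum(rec$spliced + rec$unspliced), 2L * nrow(r$pairs))
})

test_that("percent unspliced reproduces the densitometry formula", {
  out <- percent_unspliced(tibble::tibble(
    spliced_signal = c(75, 50, 60), unspliced_signal = c(25, 0, 40)))
  expect_equal(out$percent_unspliced, c(25, 0, 40))
  expect_error(percent_unspliced(tibble::tibble(spliced_signal = 0,
                                                unspliced_signal = 0)),
               "positive")
})

test_that("the null rejection rate of the comparison is near nominal", {
  cal <- splicing_null_calibration(n_genes = 100L, theta = 0.3, depth = 50L,
                                   n_reps = 300L, alpha = 0.05, seed = 5L)
  expect_gt(cal$rejection_rate, 0.02)
  expect_lt(cal$rejection_rate, 0.09)
})
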