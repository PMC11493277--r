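# The synthetic-data generator: annotation structure, read emission,
# determinism, and agreement between emitted reads and recorded truth.

test_that("annotation echoes requested class counts and structure", {
  cfg <- sim_config(seed = 1, n_genes = c(intron_containing = 3L,
                                          intronless = 2L, histone = 1L))
  sim <- simulate_annotation(cfg)
  g <- sim$annotation$genes
  expect_equal(nrow(g), 6L)
  expect_equal(sort(table(g$class)),
               sort(table(c(rep("intron_containing", 3),
                            rep("intronless", 2), "histone"))))
  expect_true(all(g$n_exons[g$class != "intron_containing"] == 1L))
  expect_true(all(g$n_exons[g$class == "intron_containing"] >= 2L))
  expect_setequal(unique(g$strand), c("+", "-"))
  # non-overlapping per chromosome
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  # intron-containing genes no longer than the longest intronless gene
  cap <- max((g$end - g$start)[g$class == "intronless"])
  expect_true(all((g$end - g$start)[g$class == "intron_containing"] <= cap))
})

test_that("fixed seed gives byte-identical annotation and reads", {
  cfg <- small_config(seed = 42)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  expect_identical(s1$annotation, s2$annotation)
  r1 <- simulate_rnaseq_pairs(s1$annotation, s1$truth, cfg, depth = 300)
  r2 <- simulate_rnaseq_pairs(s2$annotation, s2$truth, cfg, depth = 300)
  expect_identical(r1$pairs, r2$pairs)
  n1 <- simulate_netseq_pairs(s1$annotation, s1$truth, cfg, depth = 500)
  n2 <- simulate_netseq_pairs(s2$annotation, s2$truth, cfg, depth = 500)
  expect_identical(n1$pairs, n2$pairs)
})

test_that("forced exon count yields exactly two introns", {
  cfg <- small_config(seed = 3, exon_count_range = c(3L, 3L))
  g <- simulate_annotation(cfg)$annotation$genes
  expect_true(all(g$n_exons[g$class == "intron_containing"] == 3L))
})

test_that("degenerate retention probabilities emit pure read classes", {
  cfg0 <- sim_config(seed = 4, n_genes = c(intron_containing = 1L,
                                           intronless = 0L, histone = 0L),
                     intron_retention = 0)
  s0 <- simulate_annotation(cfg0)
  r0 <- simulate_rnaseq_pairs(s0$annotation, s0$truth, cfg0, depth = 1000)
  expect_equal(sum(r0$truth$genes$rnaseq_unspliced, na.rm = TRUE), 0L)
  expect_true(all(grepl("N", r0$pairs$cigar1)))

  cfg1 <- sim_config(seed = 4, n_genes = c(intron_containing = 1L,
                                           intronless = 0L, histone = 0L),
                     intron_retention = 1)
  s1 <- simulate_annotation(cfg1)
  r1 <- simulate_rnaseq_pairs(s1$annotation, s1$truth, cfg1, depth = 1000)
  expect_equal(sum(r1$truth$genes$rnaseq_spliced, na.rm = TRUE), 0L)
  expect_false(any(grepl("N", r1$pairs$cigar1)))
})

test_that("realized retention fraction is binomially consistent with theta", {
  cfg <- sim_config(seed = 7, n_genes = c(intron_containing = 1L,
                                          intronless = 0L, histone = 0L),
                    intron_retention = 0.3)
  s <- simulate_annotation(cfg)
  r <- simulate_rnaseq_pairs(s$annotation, s$truth, cfg, depth = 10000)
  tg <- r$truth$genes[s$annotation$genes$class == "intron_containing", ]
  frac <- tg$rnaseq_unspliced / (tg$rnaseq_spliced + tg$rnaseq_unspliced)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("with no pausing and no readthrough the body signal is uniform", {
  cfg <- sim_config(seed = 3,
                    n_genes = c(intron_containing = 0L, intronless = 1L,
                                histone = 0L),
                    gene_length_range = list(intron_containing = c(1000L, 10000L),
                                             intronless = c(5000L, 5000L),
                                             histone = c(400L, 1000L)),
                    pause_height = 0, readthrough_extent = 0, depth = 1e5)
  s <- simulate_annotation(cfg)
  net <- simulate_netseq_pairs(s$annotation, s$truth, cfg, depth = 1e5)
  tags <- tags_from_pairs(net$pairs, flip_strand = TRUE)
  g <- s$annotation$genes
  cell <- (tags$pos - g$start) %/% 250L
  expect_gt(chisq.test(table(cell))$p.value, 0.01)
})

test_that("treated readthrough gain produces more downstream tags (common seed)", {
  cfg <- sim_config(seed = 9, n_genes = c(intron_containing = 4L,
                                          intronless = 2L, histone = 1L),
                    depth = 1e5)
  s <- simulate_annotation(cfg)
  downstream <- function(gain) {
    net <- simulate_netseq_pairs(s$annotation, s$truth, cfg,
                                 condition = "x", readthrough_gain = gain)
    tags <- tags_from_pairs(net$pairs, flip_strand = TRUE)
    g <- s$annotation$genes[match(sub(":.*", "", tags$pair_id),
                                  s$annotation$genes$gene_id), ]
    sum(ifelse(g$strand == "+", tags$pos >= g$end, tags$pos < g$start))
  }
  expect_gt(downstream(3), downstream(1))
})

test_that("zero depth and zero genes yield empty but valid outputs", {
  cfg <- small_config(seed = 2)
  s <- simulate_annotation(cfg)
  net <- simulate_netseq_pairs(s$annotation, s$truth, cfg, depth = 0)
  expect_equal(nrow(net$pairs), 0L)
  expect_equal(net$truth$conditions$n_pairs, 0L)

  cfg0 <- sim_config(seed = 1, n_genes = c(intron_containing = 0L,
                                           intronless = 0L, histone = 0L))
  s0 <- simulate_annotation(cfg0)
  expect_equal(nrow(s0$annotation$genes), 0L)
  f <- withr::local_tempfile(fileext = ".sam")
  write_alignments(nascentr:::empty_pairs(), f, s0$annotation$chrom_sizes)
  expect_true(all(grepl("^@", readLines(f))))
})

test_that("every emitted mate CIGAR consumes exactly read_length query bases", {
  cfg <- small_config(seed = 6)
  s <- simulate_annotation(cfg)
  net <- simulate_netseq_pairs(s$annotation, s$truth, cfg, depth = 2000)
  rna <- simulate_rnaseq_pairs(s$annotation, s$truth, cfg, depth = 600)
  for (p in list(net$pairs, rna$pairs)) {
    expect_true(all(GenomicAlignments::cigarWidthAlongQuerySpace(p$cigar1) ==
                      cfg$read_length))
    expect_true(all(GenomicAlignments::cigarWidthAlongQuerySpace(p$cigar2) ==
                      cfg$read_length))
  }
})

test_that("no tag falls outside the gene plus its readthrough window", {
  cfg <- small_config(seed = 8)
  s <- simulate_annotation(cfg)
  net <- simulate_netseq_pairs(s$annotation, s$truth, cfg, depth = 5000)
  tags <- tags_from_pairs(net$pairs, flip_strand = TRUE)
  g <- s$annotation$genes[match(sub(":.*", "", tags$pair_id),
                                s$annotation$genes$gene_id), ]
  lo <- ifelse(g$strand == "+", g$start, g$start - cfg$readthrough_extent)
  hi <- ifelse(g$strand == "+", g$end + cfg$readthrough_extent, g$end)
  expect_true(all(tags$pos >= lo & tags$pos < hi))
})

test_that("infeasible packing raises an explicit error", {
  cfg <- small_config(seed = 1)
  expect_error(simulate_annotation(cfg, max_chrom_length = 5000),
               "Infeasible packing")
})

test_that("SAM round trip preserves the pair set and flag algebra", {
  cfg <- small_config(seed = 5)
  s <- simulate_annotation(cfg)
  net <- simulate_netseq_pairs(s$annotation, s$truth, cfg, depth = 800)
  f <- withr::local_tempfile(fileext = ".sam")
  write_alignments(net$pairs, f, s$annotation$chrom_sizes)

  lines <- readLines(f)
  expect_true(any(grepl("^@HD\t", lines)))
  expect_equal(sum(grepl("^@SQ\t", lines)), length(s$annotation$chrom_sizes))
  body <- lines[!grepl("^@", lines)]
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2L))
  expect_true(all(bitwAnd(flags, 1L) > 0L))     # paired
  expect_true(all(bitwAnd(flags, 2L) > 0L))     # proper
  qn <- vapply(strsplit(body, "\t"), `[`, character(1), 1L)
  first <- tapply(bitwAnd(flags, 64L) > 0L, qn, sum)
  expect_true(all(first == 1L))                 # 0x40 on exactly one mate

  back <- read_alignment_pairs(f)
  key <- function(p) paste(p$pair_id, p$chrom, p$start1, p$cigar1, p$strand1,
                           p$start2, p$cigar2, p$strand2)
  expect_setequal(key(back), key(net$pairs))
})

test_that("truth bundle JSON round-trips losslessly", {
  cfg <- small_config(seed = 12)
  s <- simulate_annotation(cfg)
  r <- simulate_rnaseq_pairs(s$annotation, s$truth, cfg, depth = 300)
  n <- simulate_netseq_pairs(s$annotation, r$truth, cfg, depth = 300)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_json(n$truth, f)
  back <- read_truth_json(f)
  expect_equal(as.data.frame(back$genes), as.data.frame(n$truth$genes))
  expect_equal(as.data.frame(back$conditions),
               as.data.frame(n$truth$conditions))
})
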