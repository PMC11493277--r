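# Scaled metagene matrices, profiles, readthrough index.

const_track <- function(value = 2, len = 20000L, strands = c("+", "-")) {
  rows <- dplyr::bind_rows(lapply(strands, function(s) {
    tibble::tibble(chrom = "c1", strand = s,
                   start = seq(0L, len - 10L, by = 10L),
                   end = seq(10L, len, by = 10L),
                   count = NA_integer_, score = value)
  }))
  structure(rows, class = c("coverage_track", class(rows)),
            bin_size = 10L, normalization = "none", library_size = 1,
            chrom_sizes = c(c1 = len))
}

test_that("a constant track yields an exactly flat matrix and profile", {
  trk <- const_track(value = 3)
  regions <- tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                            start = c(3000L, 9000L), end = c(8000L, 12000L),
                            strand = c("+", "-"))
  m <- scale_regions_matrix(trk, regions, flank_bp = 1000L, body_bins = 50L)
  expect_equal(max(m) - min(m), 0)
  prof <- mean_profile(m)
  expect_equal(max(prof$value) - min(prof$value), 0)
  expect_equal(unique(prof$value), 3)
})

test_that("a body of exactly body_bins x bin_size is passed through unscaled", {
  set.seed(7)
  vals <- runif(30)
  rows <- tibble::tibble(chrom = "c1", strand = "+",
                         start = seq(1000L, 1290L, by = 10L),
                         end = seq(1010L, 1300L, by = 10L),
                         count = NA_integer_, score = vals)
  trk <- structure(rows, class = c("coverage_track", class(rows)),
                   bin_size = 10L, normalization = "none", library_size = 1,
                   chrom_sizes = c(c1 = 5000L))
  regions <- tibble::tibble(gene_id = "r", chrom = "c1",
                            start = 1000L, end = 1300L, strand = "+")
  m <- scale_regions_matrix(trk, regions, flank_bp = 0L, body_bins = 30L)
  expect_equal(as.numeric(m[1, ]), vals)
})

test_that("two-bin body resampled to three bins gives the hand-computed values", {
  # source bins [2, 4]; overlap weights (1, 1/2 + 1/2, 1) -> [2, 3, 4]
  rows <- tibble::tibble(chrom = "c1", strand = "+",
                         start = c(100L, 110L), end = c(110L, 120L),
                         count = NA_integer_, score = c(2, 4))
  trk <- structure(rows, class = c("coverage_track", class(rows)),
                   bin_size = 10L, normalization = "none", library_size = 1,
                   chrom_sizes = c(c1 = 1000L))
  regions <- tibble::tibble(gene_id = "r", chrom = "c1",
                            start = 100L, end = 120L, strand = "+")
  m <- scale_regions_matrix(trk, regions, flank_bp = 0L, body_bins = 3L)
  expect_equal(as.numeric(m[1, ]), c(2, 3, 4))
})

test_that("body rescaling preserves the length-weighted mean (mass)", {
  set.seed(11)
  n_bins <- 40L
  rows <- tibble::tibble(chrom = "c1", strand = "+",
                         start = seq(0L, (n_bins - 1L) * 10L, by = 10L),
                         end = seq(10L, n_bins * 10L, by = 10L),
                         count = NA_integer_, score = rpois(n_bins, 5))
  trk <- structure(rows, class = c("coverage_track", class(rows)),
                   bin_size = 10L, normalization = "none", library_size = 1,
                   chrom_sizes = c(c1 = n_bins * 10L))
  regions <- tibble::tibble(gene_id = "r", chrom = "c1",
                            start = 0L, end = n_bins * 10L, strand = "+")
  for (bb in c(7L, 30L, 113L)) {
    m <- scale_regions_matrix(trk, regions, flank_bp = 0L, body_bins = bb)
    expect_equal(mean(as.numeric(m[1, ])), mean(rep(rows$score, each = 10L)))
  }
})

test_that("minus-strand regions mirror their plus-strand twins", {
  set.seed(3)
  len <- 4000L
  rows <- tibble::tibble(chrom = "c1", strand = "+",
                         start = seq(0L, len - 10L, 10L),
                         end = seq(10L, len, 10L),
                         count = NA_integer_, score = runif(len / 10L))
  rows <- dplyr::bind_rows(rows, dplyr::mutate(rows, strand = "-"))
  trk <- structure(rows, class = c("coverage_track", class(rows)),
                   bin_size = 10L, normalization = "none", library_size = 1,
                   chrom_sizes = c(c1 = len))
  regions <- tibble::tibble(gene_id = c("p", "m"), chrom = "c1",
                            start = 1000L, end = 3000L,
                            strand = c("+", "-"))
  m <- scale_regions_matrix(trk, regions, flank_bp = 500L, body_bins = 20L)
  expect_equal(as.numeric(m[1, ]), rev(as.numeric(m[2, ])))
})

test_that("flanks beyond the chromosome edge are zero-filled and flagged", {
  trk <- const_track(value = 1, len = 3000L)
  regions <- tibble::tibble(gene_id = "edge", chrom = "c1",
                            start = 200L, end = 1200L, strand = "+")
  m <- scale_regions_matrix(trk, regions, flank_bp = 1000L, body_bins = 10L)
  expect_true(attr(m, "truncated"))
  expect_equal(as.numeric(m[1, 1:80]), rep(0, 80))   # 800 bp of zero fill
  expect_equal(as.numeric(m[1, 81:100]), rep(1, 20))
})

test_that("profile averaging over replicates and rows is arithmetic", {
  mk <- function(rowvals) {
    m <- matrix(rowvals, nrow = length(rowvals), ncol = 4, byrow = FALSE)
    structure(m, class = c("metagene_matrix", "matrix", "array"),
              flank_bins = 1L, body_bins = 2L, bin_size = 10L,
              region_ids = paste0("r", seq_along(rowvals)),
              truncated = rep(FALSE, length(rowvals)))
  }
  one <- mk(5)
  expect_equal(mean_profile(one)$value, rep(5, 4))
  reps <- list(mk(c(0, 2)), mk(c(4, 6)))
  expect_equal(mean_profile(reps)$value, rep(mean(c(1, 5)), 4))
  expect_equal(mean_profile(list(reps[[1]], reps[[1]]))$value,
               mean_profile(reps[[1]])$value)
  bad <- mk(1); attr(bad, "body_bins") <- 3L
  expect_error(mean_profile(list(one, bad)), "geometry")
})

test_that("readthrough index is 1 on uniform signal and 0 without tail", {
  trk <- const_track(value = 2, len = 20000L)
  gene <- tibble::tibble(gene_id = "g", chrom = "c1", strand = "+",
                         start = 5000L, end = 10000L)
  rt <- readthrough_index(trk, gene, downstream_window_bp = 2000L,
                          body_excl_bp = 500L)
  expect_equal(rt$index, 1)

  # zero signal downstream of the poly(A) site
  rows <- tibble::tibble(chrom = "c1", strand = "+",
                         start = seq(5000L, 9990L, 10L),
                         end = seq(5010L, 10000L, 10L),
                         count = NA_integer_, score = 2)
  trk0 <- structure(rows, class = c("coverage_track", class(rows)),
                    bin_size = 10L, normalization = "none", library_size = 1,
                    chrom_sizes = c(c1 = 20000L))
  expect_equal(readthrough_index(trk0, gene)$index, 0)
  expect_error(readthrough_index(trk, gene, downstream_window_bp = 0L),
               "positive")
})
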