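#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: how many genes of
#' each class to draw, their length distributions, the per-gene intron
#' retention probability, the polymerase occupancy model (promoter-proximal
#' pause peak, uniform gene-body density, exponential readthrough tail past
#' the poly(A) site), and the sequencing geometry (insert size range, read
#' length, total pair depth).
#'
#' The defaults mirror the analyzed gene set of a typical HeLa nascent
#' transcription study: 2,236 intron-containing, 193 intronless and 40
#' histone genes, 35-100 nt size-selected inserts sequenced as paired
#' 100 nt reads.
#'
#' @param seed Integer seed; every generator operation derives its own RNG
#'   stream from it, so outputs are bit-identical across runs.
#' @param n_genes Named integer vector with elements `intron_containing`,
#'   `intronless` and `histone` (counts may be zero).
#' @param gene_length_range Named list of length-2 integer vectors (bp), one
#'   per class. Intron-containing lengths are additionally capped at the
#'   longest generated intronless gene so the class-size cap rule downstream
#'   is exercised non-trivially.
#' @param exon_count_range Length-2 integer vector; exon count drawn
#'   uniformly for intron-containing genes (minimum 2). Intronless and
#'   histone genes always have exactly one exon.
#' @param intron_retention Per-gene probability theta that a
#'   junction-spanning RNA-seq fragment is emitted intron-retaining
#'   (unspliced). Scalar (recycled) or one value per intron-containing gene.
#' @param pause_height Pause-peak height as a dimensionless multiple of the
#'   gene-body density.
#' @param pause_width Pause-peak Gaussian width (bp, standard deviation).
#' @param body_density Expected tags per kb of gene body; sets the relative
#'   sequencing mass of genes of different lengths.
#' @param readthrough_extent How far past the poly(A) site (bp) tags may be
#'   emitted.
#' @param readthrough_decay Exponential length constant (bp) of the
#'   post-poly(A) tail.
#' @param readthrough_gain Multiplier on the readthrough tail used for a
#'   "termination-defect" (treated) condition; the control condition uses 1.
#' @param insert_range Length-2 integer vector, mNET-seq insert (RNA
#'   fragment) size range in bp; default 35-100.
#' @param read_length Sequenced read length (bp). Inserts shorter than the
#'   read are soft-clipped so every mate's CIGAR consumes exactly
#'   `read_length` query bases.
#' @param depth Total read pairs per simulated library.
#' @param intergenic_gap Length-2 numeric vector, bp gap drawn uniformly
#'   between consecutive genes when packing the synthetic chromosomes.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = c(intron_containing = 3,
#'                                         intronless = 2, histone = 1))
#' cfg$depth
#' @export
sim_config <- function(seed = 1L,
                       n_genes = c(intron_containing = 2236L,
                                   intronless = 193L,
                                   histone = 40L),
                       gene_length_range = list(
                         intron_containing = c(1000L, 10000L),
                         intronless = c(500L, 10000L),
                         histone = c(400L, 1000L)),
                       exon_count_range = c(3L, 12L),
                       intron_retention = 0.15,
                       pause_height = 10,
                       pause_width = 150,
                       body_density = 10,
                       readthrough_extent = 5000,
                       readthrough_decay = 2000,
                       readthrough_gain = 3,
                       insert_range = c(35L, 100L),
                       read_length = 100L,
                       depth = 1e6,
                       intergenic_gap = c(2000, 8000)) {
  classes <- c("intron_containing", "intronless", "histone")
  n_genes <- n_genes[classes]
  if (anyNA(n_genes) || any(n_genes < 0)) {
    abort("`n_genes` must give a non-negative count for each of: intron_containing, intronless, histone.")
  }
  for (cl in classes) {
    r <- gene_length_range[[cl]]
    if (is.null(r) || length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      abort(paste0("`gene_length_range$", cl, "` must be a valid positive bp range."))
    }
  }
  if (length(exon_count_range) != 2L || exon_count_range[1] < 2L ||
      exon_count_range[1] > exon_count_range[2]) {
    abort("`exon_count_range` must be an increasing pair with minimum >= 2.")
  }
  if (any(intron_retention < 0 | intron_retention > 1)) {
    abort("`intron_retention` must lie in [0, 1].")
  }
  if (pause_height < 0 || pause_width <= 0 || body_density <= 0) {
    abort("Occupancy parameters must be positive (pause_height may be 0).")
  }
  if (readthrough_extent < 0 || readthrough_decay <= 0 || any(readthrough_gain < 0)) {
    abort("Readthrough parameters must be non-negative (decay strictly positive).")
  }
  if (length(insert_range) != 2L || insert_range[1] < 1L ||
      insert_range[1] > insert_range[2]) {
    abort("`insert_range` must be an increasing pair of positive bp values.")
  }
  if (read_length < 1L) abort("`read_length` must be a positive integer.")
  if (depth < 0) abort("`depth` must be >= 0.")
  if (length(intergenic_gap) != 2L || any(intergenic_gap < 0) ||
      intergenic_gap[1] > intergenic_gap[2]) {
    abort("`intergenic_gap` must be a non-decreasing pair of non-negative bp values.")
  }

  structure(list(
    seed = as.integer(seed),
    n_genes = setNames(as.integer(n_genes), classes),
    gene_length_range = lapply(gene_length_range[classes], as.integer),
    exon_count_range = as.integer(exon_count_range),
    intron_retention = as.numeric(intron_retention),
    pause_height = pause_height,
    pause_width = pause_width,
    body_density = body_density,
    readthrough_extent = as.integer(readthrough_extent),
    readthrough_decay = readthrough_decay,
    readthrough_gain = readthrough_gain,
    insert_range = as.integer(insert_range),
    read_length = as.integer(read_length),
    depth = depth,
    intergenic_gap = as.numeric(intergenic_gap)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " depth:", format(x$depth, big.mark = ","), "\n")
  cat("  genes:", paste(names(x$n_genes), x$n_genes, sep = "=", collapse = " "), "\n")
  cat("  occupancy: pause", x$pause_height, "x body /", x$pause_width,
      "bp; body", x$body_density, "tags/kb; tail decay",
      x$readthrough_decay, "bp over", x$readthrough_extent, "bp\n")
  cat("  reads:", paste(x$insert_range, collapse = "-"), "nt inserts,",
      x$read_length, "nt mates\n")
  invisible(x)
}
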