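#' Simulate a gene annotation with known class structure
#'
#' Draws genes of the three transcription-unit classes (intron-containing,
#' intronless, histone) with class-specific length distributions, packs them
#' without overlap onto two synthetic chromosomes using both strands, and
#' builds the matching truth bundle (per-gene class, intron-retention
#' probability and occupancy parameters) that downstream simulators update
#' with realized read counts.
#'
#' Intronless and histone genes have exactly one exon. Intron-containing
#' genes receive an exon count drawn from `config$exon_count_range` and a
#' random exon/intron partition of their span; their genomic length is
#' capped at the longest generated intronless gene (when any intronless
#' genes are requested), so the downstream length-cap classification rule is
#' exercised non-trivially.
#'
#' @param config A [sim_config()].
#' @param max_chrom_length Maximum synthetic chromosome length in bp; if the
#'   packed genes (plus intergenic gaps and readthrough margin) exceed it,
#'   an infeasible-packing error is raised.
#'
#' @return A list with components
#'   * `annotation`: class `gene_annotation`; a list of `genes` (tibble:
#'     `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`,
#'     `class`, `n_exons`; 0-based half-open coordinates), `exons` (tibble:
#'     one row per exon with `exon_rank` in transcription order) and
#'     `chrom_sizes` (named integer vector).
#'   * `truth`: class `truth_bundle`; per-gene truth parameters plus realized
#'     count columns (initialised to `NA`) and the generating config.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = c(intron_containing = 3,
#'                                         intronless = 2, histone = 1))
#' sim <- simulate_annotation(cfg)
#' sim$annotation$genes
#' @export
simulate_annotation <- function(config, max_chrom_length = 2^28) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- sum(config$n_genes)
  chroms <- c("chrS1", "chrS2")

  if (n_total == 0L) {
    genes <- tibble(gene_id = character(), transcript_id = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer(),
                    class = character(), n_exons = integer())
    exons <- tibble(gene_id = character(), transcript_id = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer(), exon_rank = integer())
    ann <- new_gene_annotation(genes, exons,
                               setNames(rep(100000L, 2L), chroms))
    return(list(annotation = ann, truth = new_truth_bundle(genes, config)))
  }

  with_op_seed(config$seed, OP_SEED_ANNOTATION, {
    classes <- rep(names(config$n_genes), times = config$n_genes)
    classes <- sample(classes)                       # interleave classes

    # Lengths: intronless first, then cap intron-containing at their maximum.
    len <- integer(length(classes))
    for (cl in c("intronless", "histone")) {
      idx <- which(classes == cl)
      r <- config$gene_length_range[[cl]]
      len[idx] <- resample(seq.int(r[1], r[2]), length(idx))
    }
    idx_ic <- which(classes == "intron_containing")
    if (length(idx_ic)) {
      r <- config$gene_length_range$intron_containing
      cap <- if (any(classes == "intronless")) {
        max(len[classes == "intronless"])
      } else r[2]
      hi <- min(r[2], cap)
      if (hi < r[1]) {
        abort("Intron-containing length range is incompatible with the intronless length cap.")
      }
      len[idx_ic] <- resample(seq.int(r[1], hi), length(idx_ic))
    }

    gene_id <- sprintf("G%05d", seq_along(classes))
    transcript_id <- paste0(gene_id, ".T1")
    strand <- rep_len(c("+", "-"), length(classes))
    chrom <- rep_len(chroms, length(classes))

    # Pack each chromosome left to right with random intergenic gaps and a
    # readthrough margin at both ends.
    margin <- config$readthrough_extent + 1000L
    start <- integer(length(classes))
    chrom_sizes <- setNames(integer(length(chroms)), chroms)
    for (ch in chroms) {
      idx <- which(chrom == ch)
      gaps <- round(runif(length(idx), config$intergenic_gap[1],
                          config$intergenic_gap[2]))
      pos <- margin
      for (k in seq_along(idx)) {
        start[idx[k]] <- pos
        pos <- pos + len[idx[k]] + gaps[k]
      }
      chrom_sizes[ch] <- pos + margin
      if (chrom_sizes[ch] > max_chrom_length) {
        abort(paste0("Infeasible packing: total gene span on ", ch, " (",
                     chrom_sizes[ch], " bp) exceeds the maximum chromosome length (",
                     max_chrom_length, " bp)."))
      }
    }
    end <- start + len

    # Exon structure.
    n_exons <- rep(1L, length(classes))
    if (length(idx_ic)) {
      n_exons[idx_ic] <- resample(seq.int(config$exon_count_range[1],
                                          config$exon_count_range[2]),
                                  length(idx_ic))
    }
    min_seg <- 30L
    exon_rows <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      k <- n_exons[i]
      if (k == 1L) {
        seg_start <- start[i]; seg_end <- end[i]
        ranks <- 1L
      } else {
        n_seg <- 2L * k - 1L
        while (len[i] < min_seg * n_seg && k > 2L) {   # keep partition feasible
          k <- k - 1L; n_seg <- 2L * k - 1L
        }
        n_exons[i] <- k
        w <- runif(n_seg, 0.2, 1)
        seg <- pmax(min_seg, floor(w / sum(w) * len[i]))
        seg[n_seg] <- len[i] - sum(seg[-n_seg])
        if (seg[n_seg] < min_seg) {                     # rebalance the tail
          need <- min_seg - seg[n_seg]
          seg[1L] <- seg[1L] - need
          seg[n_seg] <- min_seg
        }
        bounds <- start[i] + c(0L, cumsum(seg))
        exon_idx <- seq(1L, n_seg, by = 2L)
        seg_start <- bounds[exon_idx]
        seg_end <- bounds[exon_idx + 1L]
        ranks <- seq_len(k)
        if (strand[i] == "-") ranks <- rev(ranks)       # transcription order
      }
      exon_rows[[i]] <- tibble(
        gene_id = gene_id[i], transcript_id = transcript_id[i],
        chrom = chrom[i], strand = strand[i],
        start = as.integer(seg_start), end = as.integer(seg_end),
        exon_rank = as.integer(ranks))
    }
    exons <- bind_rows(exon_rows) |> arrange(.data$chrom, .data$start)

    genes <- tibble(gene_id = gene_id, transcript_id = transcript_id,
                    chrom = chrom, strand = strand,
                    start = as.integer(start), end = as.integer(end),
                    class = classes, n_exons = n_exons) |>
      arrange(.data$chrom, .data$start)

    ann <- new_gene_annotation(genes, exons, chrom_sizes)
    list(annotation = ann, truth = new_truth_bundle(genes, config))
  })
}

new_gene_annotation <- function(genes, exons, chrom_sizes) {
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation>", nrow(x$genes), "genes /", nrow(x$exons),
      "exons on", length(x$chrom_sizes), "chromosome(s)\n")
  print(dplyr::count(x$genes, .data$class))
  invisible(x)
}

new_truth_bundle <- function(genes, config) {
  n_ic <- sum(genes$class == "intron_containing")
  theta <- rep(NA_real_, nrow(genes))
  if (n_ic > 0) {
    theta[genes$class == "intron_containing"] <-
      rep_len(config$intron_retention, n_ic)
  }
  gt <- tibble(
    gene_id = genes$gene_id,
    class = genes$class,
    theta = theta,
    pause_height = config$pause_height,
    body_density = config$body_density,
    readthrough_extent = config$readthrough_extent,
    readthrough_decay = config$readthrough_decay,
    rnaseq_spliced = NA_integer_,
    rnaseq_unspliced = NA_integer_
  )
  structure(list(genes = gt,
                 conditions = tibble(condition = character(),
                                     readthrough_gain = numeric(),
                                     pause_height = numeric(),
                                     body_density = numeric(),
                                     n_pairs = integer()),
                 config = unclass(config)),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle>", nrow(x$genes), "genes;",
      nrow(x$conditions), "simulated condition(s)\n")
  invisible(x)
}

#' Serialize / restore a truth bundle
#'
#' The truth bundle round-trips losslessly through JSON so a simulation can
#' be audited or re-loaded without R serialization formats.
#'
#' @param truth A `truth_bundle`.
#' @param path File path for the JSON document.
#' @return `write_truth_json()` returns `path` invisibly;
#'   `read_truth_json()` returns the restored `truth_bundle`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_bundle"))
  jsonlite::write_json(
    list(genes = truth$genes, conditions = truth$conditions,
         config = truth$config),
    path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  cfg$gene_length_range <- lapply(cfg$gene_length_range, as.integer)
  for (f in c("n_genes")) cfg[[f]] <- unlist(cfg[[f]])
  genes <- as_tibble(x$genes)
  genes$rnaseq_spliced <- as.integer(genes$rnaseq_spliced)
  genes$rnaseq_unspliced <- as.integer(genes$rnaseq_unspliced)
  conditions <- as_tibble(x$conditions)
  if (nrow(conditions) == 0L) {
    conditions <- tibble(condition = character(), readthrough_gain = numeric(),
                         pause_height = numeric(), body_density = numeric(),
                         n_pairs = integer())
  }
  structure(list(genes = genes, conditions = conditions, config = cfg),
            class = "truth_bundle")
}
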