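# Paired-end read simulators.
#
# A "pairs" tibble has one row per read pair with 0-based leftmost positions:
#   pair_id, chrom, start1, cigar1, strand1, start2, cigar2, strand2,
#   proper, mapped1, mapped2, gene_id
# Mate 1 / mate 2 carry SAM flags 0x40 / 0x80 when written out.

empty_pairs <- function() {
  tibble(pair_id = character(), chrom = character(),
         start1 = integer(), cigar1 = character(), strand1 = character(),
         start2 = integer(), cigar2 = character(), strand2 = character(),
         proper = logical(), mapped1 = logical(), mapped2 = logical(),
         gene_id = character())
}

# Exon table of one transcript (genomic ascending) -> transcription-order map.
tx_map <- function(exons_gene) {
  stopifnot(nrow(exons_gene) >= 1L)
  strand <- exons_gene$strand[1]
  ord <- if (strand == "+") order(exons_gene$start) else order(-exons_gene$start)
  ex <- exons_gene[ord, , drop = FALSE]
  w <- ex$end - ex$start
  list(strand = strand, start = ex$start, end = ex$end, width = w,
       cum0 = cumsum(c(0L, w))[seq_along(w)], tx_len = sum(w))
}

# Transcript interval [a, b) -> genomic blocks (ascending), as a 2-col matrix.
tx_to_blocks <- function(map, a, b) {
  hit <- which(map$cum0 < b & (map$cum0 + map$width) > a)
  gs <- ge <- numeric(length(hit))
  for (k in seq_along(hit)) {
    i <- hit[k]
    lo <- max(a, map$cum0[i]); hi <- min(b, map$cum0[i] + map$width[i])
    if (map$strand == "+") {
      gs[k] <- map$start[i] + (lo - map$cum0[i])
      ge[k] <- map$start[i] + (hi - map$cum0[i])
    } else {
      ge[k] <- map$end[i] - (lo - map$cum0[i])
      gs[k] <- map$end[i] - (hi - map$cum0[i])
    }
  }
  ord <- order(gs)
  cbind(start = gs[ord], end = ge[ord])
}

# Genomic blocks -> CIGAR (M runs joined by N gaps) with an optional soft
# clip at the read's 3' end: trailing for forward reads, leading for reverse
# (SAM stores reverse reads reverse-complemented, so their 3' end is
# reference-left).
blocks_to_cigar <- function(blocks, clip = 0L, orientation = "+") {
  m <- blocks[, "end"] - blocks[, "start"]
  gaps <- if (nrow(blocks) > 1L) blocks[-1L, "start"] - blocks[-nrow(blocks), "end"] else numeric(0)
  core <- paste0(m[1], "M")
  if (length(gaps)) {
    core <- paste0(core, paste0(gaps, "N", m[-1L], "M", collapse = ""))
  }
  if (clip > 0L) {
    core <- if (orientation == "+") paste0(core, clip, "S") else paste0(clip, "S", core)
  }
  core
}

#' Simulate junction-anchored RNA-seq read pairs with known intron retention
#'
#' For every intron-containing gene, emits `depth / n_genes` fragments
#' anchored on a randomly chosen internal splice junction. With the gene's
#' retention probability theta the fragment is emitted intron-retaining
#' (genomic-contiguous, CIGAR without an N operation); otherwise it is
#' spliced (mates carry an N operation spanning the intron). Fragment
#' placement guarantees that *both* mates cross the junction with at least
#' `min_overhang` aligned bases on each side, so each read's CIGAR class
#' reflects the fragment's retention status. Single-exon genes receive
#' plain exonic fragments.
#'
#' Pairs are convergent and strand-specific: mate 1 is the sense read, so
#' its alignment orientation equals the transcript strand.
#'
#' @param annotation,truth Output of [simulate_annotation()].
#' @param config The generating [sim_config()]; `config$intron_retention`
#'   (recycled over intron-containing genes) defines per-gene theta.
#' @param depth Total pairs across all genes (default `config$depth`).
#' @param insert_range RNA-seq fragment length range in bp. The default
#'   keeps fragments shorter than two read lengths so both mates can span
#'   the anchor junction.
#' @param read_length Mate length in bp (default `config$read_length`).
#' @param min_overhang Minimum aligned bases on each side of the junction.
#' @param max_retries Resampling attempts for infeasible fragments before
#'   erroring.
#'
#' @return A list with `pairs` (the pairs tibble) and `truth` (the input
#'   truth bundle with realized per-gene `rnaseq_spliced` /
#'   `rnaseq_unspliced` pair counts filled in).
#' @export
simulate_rnaseq_pairs <- function(annotation, truth, config,
                                  depth = config$depth,
                                  insert_range = c(130L, 180L),
                                  read_length = config$read_length,
                                  min_overhang = 8L,
                                  max_retries = 50L) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(truth, "truth_bundle"),
            inherits(config, "sim_config"))
  genes <- annotation$genes
  if (nrow(genes) == 0L || depth <= 0) {
    return(list(pairs = empty_pairs(), truth = truth))
  }
  rl <- as.integer(read_length)
  n_per_gene <- max(1L, round(depth / nrow(genes)))

  with_op_seed(config$seed, OP_SEED_RNASEQ, {
    out <- vector("list", nrow(genes))
    spliced_n <- unspliced_n <- integer(nrow(genes))

    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, , drop = FALSE]
      map <- tx_map(ex)
      theta <- truth$genes$theta[match(g$gene_id, truth$genes$gene_id)]
      n <- n_per_gene

      if (g$n_exons < 2L) {
        # Exonic fragments only; all unspliced by CIGAR.
        L <- sample.int(insert_range[2] - insert_range[1] + 1L, n, replace = TRUE) +
          insert_range[1] - 1L
        L <- pmin(L, g$end - g$start)
        g0 <- g$start + floor(runif(n) * (g$end - g$start - L + 1))
        al <- pmin(L, rl); clip <- rl - al
        fwd_start <- g0; rev_start <- g0 + L - al
        cig_f <- paste0(al, "M", ifelse(clip > 0, paste0(clip, "S"), ""))
        cig_r <- paste0(ifelse(clip > 0, paste0(clip, "S"), ""), al, "M")
        if (g$strand == "+") {
          p <- tibble(start1 = as.integer(fwd_start), cigar1 = cig_f, strand1 = "+",
                      start2 = as.integer(rev_start), cigar2 = cig_r, strand2 = "-")
        } else {
          p <- tibble(start1 = as.integer(rev_start), cigar1 = cig_r, strand1 = "-",
                      start2 = as.integer(fwd_start), cigar2 = cig_f, strand2 = "+")
        }
        out[[gi]] <- mutate(p,
          pair_id = sprintf("%s:R%06d", g$gene_id, seq_len(n)),
          chrom = g$chrom, proper = TRUE, mapped1 = TRUE, mapped2 = TRUE,
          gene_id = g$gene_id)
        unspliced_n[gi] <- n
        next
      }

      # Junction-anchored fragments.
      jct_tx <- cumsum(map$width)[-length(map$width)]   # junction tx coords
      retained <- runif(n) < theta
      rows <- vector("list", n)
      for (f in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          L <- resample(seq.int(insert_range[1], insert_range[2]), 1L)
          if (L > map$tx_len || L < 2L * min_overhang) next
          al <- min(L, rl); clip <- rl - al
          j <- if (length(jct_tx) == 1L) 1L else sample(length(jct_tx), 1L)
          tj <- jct_tx[j]
          # Both mates must cross tj with min_overhang; mates are the first
          # and last `al` bases of the fragment.
          lo <- max(0, tj - al + min_overhang, tj + min_overhang - L)
          hi <- min(map$tx_len - L, tj - min_overhang,
                    tj + al - min_overhang - L)
          if (hi < lo) next
          t0 <- lo + floor(runif(1) * (hi - lo + 1))

          if (retained[f]) {
            # Pre-mRNA (genomic-contiguous) fragment crossing the exon/intron
            # boundary that corresponds to junction j.
            b <- if (g$strand == "+") map$end[j] else map$start[j]
            glo <- max(g$start, b - al + min_overhang, b + min_overhang - L)
            ghi <- min(g$end - L, b - min_overhang, b + al - min_overhang - L)
            if (ghi < glo) next
            g0 <- glo + floor(runif(1) * (ghi - glo + 1))
            b1 <- cbind(start = g0, end = g0 + al)
            b2 <- cbind(start = g0 + L - al, end = g0 + L)
          } else {
            b1 <- tx_to_blocks(map, t0, t0 + al)
            b2 <- tx_to_blocks(map, t0 + L - al, t0 + L)
          }
          # Mate1 = sense (covers fragment 5' end), mate2 = antisense.
          sense_blocks <- b1; anti_blocks <- b2
          if (g$strand == "+") {
            rows[[f]] <- list(
              start1 = sense_blocks[1, "start"],
              cigar1 = blocks_to_cigar(sense_blocks, clip, "+"), strand1 = "+",
              start2 = anti_blocks[1, "start"],
              cigar2 = blocks_to_cigar(anti_blocks, clip, "-"), strand2 = "-")
          } else {
            rows[[f]] <- list(
              start1 = sense_blocks[1, "start"],
              cigar1 = blocks_to_cigar(sense_blocks, clip, "-"), strand1 = "-",
              start2 = anti_blocks[1, "start"],
              cigar2 = blocks_to_cigar(anti_blocks, clip, "+"), strand2 = "+")
          }
          ok <- TRUE
          break
        }
        if (!ok) {
          abort(paste0("Could not place a junction fragment on gene ",
                       g$gene_id, " after ", max_retries, " retries."))
        }
      }
      p <- dplyr::bind_rows(lapply(rows, as_tibble))
      out[[gi]] <- mutate(p,
        start1 = as.integer(.data$start1), start2 = as.integer(.data$start2),
        pair_id = sprintf("%s:R%06d", g$gene_id, seq_len(n)),
        chrom = g$chrom, proper = TRUE, mapped1 = TRUE, mapped2 = TRUE,
        gene_id = g$gene_id)
      spliced_n[gi] <- sum(!retained)
      unspliced_n[gi] <- sum(retained)
    }

    truth$genes$rnaseq_spliced <- spliced_n
    truth$genes$rnaseq_unspliced <- unspliced_n
    pairs <- bind_rows(out) |>
      select("pair_id", "chrom", "start1", "cigar1", "strand1",
             "start2", "cigar2", "strand2", "proper", "mapped1", "mapped2",
             "gene_id")
    list(pairs = pairs, truth = truth)
  })
}

#' Simulate mNET-seq read pairs from a polymerase occupancy model
#'
#' Draws single-nucleotide polymerase positions from each gene's occupancy
#' density -- a Gaussian pause peak at the TSS (`pause_height` times the
#' body density, width `pause_width`), a uniform gene-body component, and an
#' exponential readthrough tail past the poly(A) site (length constant
#' `readthrough_decay` over `readthrough_extent` bp, scaled by
#' `readthrough_gain`) -- and emits one convergent, properly paired read
#' pair per position. Insert sizes are uniform on `config$insert_range`;
#' inserts shorter than the read length are soft-clipped so each mate's
#' CIGAR consumes exactly `read_length` query bases.
#'
#' Library chemistry: mate 2 is the sense read covering the whole insert, so
#' its 3'-terminal aligned base is the polymerase position; mate 1 is the
#' antisense read. Consequently mate 1's alignment orientation is the
#' *reverse* of the transcript strand and tag extraction from these pairs
#' uses `flip_strand = TRUE` (see [tag_from_pair()]).
#'
#' @inheritParams simulate_rnaseq_pairs
#' @param condition Label of the simulated condition (e.g. `"control"`,
#'   `"treated"`); recorded in the truth bundle.
#' @param readthrough_gain Tail multiplier for this condition; default 1 for
#'   `"control"`, `config$readthrough_gain` otherwise.
#' @param pause_height,body_density Occupancy overrides for this condition;
#'   default the config values.
#' @param depth Total pairs (default `config$depth`).
#'
#' @return A list with `pairs` (pairs tibble; `gene_id` carries provenance)
#'   and `truth` (with a row describing this condition appended).
#' @export
simulate_netseq_pairs <- function(annotation, truth, config,
                                  condition = "control",
                                  readthrough_gain = NULL,
                                  pause_height = config$pause_height,
                                  body_density = config$body_density,
                                  depth = config$depth) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(truth, "truth_bundle"),
            inherits(config, "sim_config"))
  if (is.null(readthrough_gain)) {
    readthrough_gain <- if (identical(condition, "control")) 1 else config$readthrough_gain
  }
  genes <- annotation$genes
  record_condition <- function(tr, n) {
    tr$conditions <- bind_rows(tr$conditions, tibble(
      condition = condition, readthrough_gain = readthrough_gain,
      pause_height = pause_height, body_density = body_density,
      n_pairs = as.integer(n)))
    tr
  }
  if (nrow(genes) == 0L || depth <= 0) {
    return(list(pairs = empty_pairs(), truth = record_condition(truth, 0L)))
  }
  rl <- config$read_length
  extent <- config$readthrough_extent
  decay <- config$readthrough_decay

  gene_weights <- function(len) {
    d <- seq.int(0L, len + extent - 1L)
    w <- numeric(length(d))
    body <- d < len
    w[body] <- 1 + pause_height * exp(-0.5 * (d[body] / config$pause_width)^2)
    w[!body] <- readthrough_gain * exp(-(d[!body] - len) / decay)
    w
  }

  with_op_seed(config$seed, OP_SEED_NETSEQ, {
    lens <- genes$end - genes$start
    w_list <- lapply(lens, gene_weights)
    mass <- body_density / 1000 * vapply(w_list, sum, numeric(1))
    n_g <- as.vector(stats::rmultinom(1L, size = depth, prob = mass))

    out <- vector("list", nrow(genes))
    for (gi in seq_len(nrow(genes))) {
      n <- n_g[gi]
      if (n == 0L) next
      g <- genes[gi, ]
      d <- sample.int(length(w_list[[gi]]), n, replace = TRUE,
                      prob = w_list[[gi]]) - 1L
      L <- sample.int(config$insert_range[2] - config$insert_range[1] + 1L,
                      n, replace = TRUE) + config$insert_range[1] - 1L
      L <- pmin(L, d + 1L)                      # nascent RNA starts at the TSS
      al <- pmin(L, rl)
      clip <- rl - al
      cig_f <- paste0(al, "M", ifelse(clip > 0, paste0(clip, "S"), ""))
      cig_r <- paste0(ifelse(clip > 0, paste0(clip, "S"), ""), al, "M")
      if (g$strand == "+") {
        p <- g$start + d                        # polymerase position
        s <- p - L + 1L                         # RNA 5' end
        pairs <- tibble(
          start1 = as.integer(p - al + 1L), cigar1 = cig_r, strand1 = "-",
          start2 = as.integer(s), cigar2 = cig_f, strand2 = "+")
      } else {
        p <- g$end - 1L - d
        e <- p + L - 1L                         # RNA 5' end (genomic right)
        pairs <- tibble(
          start1 = as.integer(p), cigar1 = cig_f, strand1 = "+",
          start2 = as.integer(e - al + 1L), cigar2 = cig_r, strand2 = "-")
      }
      out[[gi]] <- mutate(pairs,
        pair_id = sprintf("%s:%s:N%06d", g$gene_id, condition, seq_len(n)),
        chrom = g$chrom, proper = TRUE, mapped1 = TRUE, mapped2 = TRUE,
        gene_id = g$gene_id)
    }
    pairs <- bind_rows(out)
    if (nrow(pairs) == 0L) pairs <- empty_pairs() else {
      pairs <- select(pairs, "pair_id", "chrom", "start1", "cigar1", "strand1",
                      "start2", "cigar2", "strand2", "proper", "mapped1",
                      "mapped2", "gene_id")
    }
    list(pairs = pairs, truth = record_condition(truth, nrow(pairs)))
  })
}
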