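# Scaled-gene metagene matrices, profiles and the readthrough index.

#' Scaled-regions metagene matrix
#'
#' For every region, takes `flank_bp` of unscaled signal on each side
#' (binned at `bin_size`) and rescales the region body to exactly
#' `body_bins` bins by length-weighted averaging of the overlapping source
#' signal, so a constant track stays constant and total body mass is
#' preserved. Rows of minus-strand regions are reversed so all rows read
#' 5' to 3'. Windows truncated at chromosome edges are zero-filled and
#' flagged.
#'
#' @param track A `coverage_track` (profiles are normally computed on RPKM
#'   tracks).
#' @param regions Tibble with `gene_id` (or `region_id`), `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @param flank_bp Unscaled flank on each side, bp.
#' @param body_bins Number of scaled body bins (> 0).
#' @param bin_size Flank bin width, bp.
#' @param strand_specific Use only track rows whose strand matches the
#'   region's strand (set `FALSE` for unstranded tracks).
#' @return A `metagene_matrix`: numeric matrix (regions x bins) with
#'   attributes `flank_bins`, `body_bins`, `bin_size`, `region_ids`,
#'   `truncated` (logical per region).
#' @export
scale_regions_matrix <- function(track, regions, flank_bp = 2000L,
                                 body_bins = 100L, bin_size = 10L,
                                 strand_specific = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  if (body_bins <= 0L) abort("`body_bins` must be a positive integer.")
  if (flank_bp %% bin_size != 0L) {
    abort("`flank_bp` must be a multiple of `bin_size`.")
  }
  regions <- as_tibble(regions)
  id_col <- intersect(c("region_id", "gene_id"), names(regions))[1]
  if (is.na(id_col)) abort("`regions` needs a `gene_id` or `region_id` column.")
  chrom_sizes <- attr(track, "chrom_sizes")
  flank_bins <- as.integer(flank_bp / bin_size)
  n_bins <- 2L * flank_bins + body_bins
  mat <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  truncated <- logical(nrow(regions))

  bin_means <- function(x, width) {
    if (length(x) == 0L) return(numeric(0))
    colMeans(matrix(x, nrow = width))
  }

  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    w_start <- r$start - flank_bp
    w_end <- r$end + flank_bp
    chrom_len <- unname(chrom_sizes[r$chrom]) %0% NA_integer_
    if (is.na(chrom_len)) abort(paste0("Region chromosome not in track: ", r$chrom))
    truncated[i] <- w_start < 0L || w_end > chrom_len
    strand <- if (strand_specific) r$strand else "*"
    # Zero-fill outside the chromosome; track_window already zero-fills
    # beyond recorded bins, so clamp then pad.
    lo <- max(w_start, 0L); hi <- min(w_end, chrom_len)
    sig <- c(numeric(max(0L, -w_start)),
             track_window(track, r$chrom, lo, hi, strand = strand),
             numeric(max(0L, w_end - chrom_len)))
    up <- if (flank_bp > 0L) bin_means(sig[seq_len(flank_bp)], bin_size) else numeric(0)
    body <- sig[(flank_bp + 1L):(flank_bp + (r$end - r$start))]
    down <- if (flank_bp > 0L) {
      bin_means(sig[(length(sig) - flank_bp + 1L):length(sig)], bin_size)
    } else numeric(0)
    row <- c(up, resample_mean(body, body_bins), down)
    if (r$strand == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- regions[[id_col]]
  structure(mat, class = c("metagene_matrix", "matrix", "array"),
            flank_bins = flank_bins, body_bins = body_bins,
            bin_size = as.integer(bin_size),
            region_ids = regions[[id_col]], truncated = truncated)
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("<metagene_matrix>", nrow(x), "regions x", ncol(x), "bins (",
      attr(x, "flank_bins"), "flank +", attr(x, "body_bins"), "body +",
      attr(x, "flank_bins"), "flank )\n")
  invisible(x)
}

#' @export
tidy.metagene_matrix <- function(x, ...) {
  fb <- attr(x, "flank_bins"); bb <- attr(x, "body_bins")
  seg <- c(rep("upstream", fb), rep("body", bb), rep("downstream", fb))
  tibble(region_id = rep(rownames(x), each = ncol(x)),
         bin = rep(seq_len(ncol(x)), nrow(x)),
         segment = rep(seg, nrow(x)),
         value = as.vector(t(unclass(x))))
}

metagene_geometry <- function(m) {
  c(flank_bins = attr(m, "flank_bins"), body_bins = attr(m, "body_bins"),
    bin_size = attr(m, "bin_size"))
}

#' Average metagene profile over regions and replicates
#'
#' Column-wise mean over regions within each matrix, then the mean across
#' replicate matrices (all matrices must share bin geometry).
#'
#' @param matrices A `metagene_matrix` or a list of them (replicates).
#' @return A `metagene_profile` tibble: `bin`, `segment`, `position`
#'   (bin centre, bp relative to the region start for flanks; body bins are
#'   fractional 0-1 positions scaled to `body_bins` columns), `value`.
#' @export
mean_profile <- function(matrices) {
  if (inherits(matrices, "metagene_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  geo <- metagene_geometry(matrices[[1]])
  for (m in matrices) {
    if (!identical(metagene_geometry(m), geo)) {
      abort("Metagene matrices have mismatched bin geometry.")
    }
  }
  per_rep <- vapply(matrices, function(m) colMeans(unclass(m)),
                    numeric(sum(geo[c("flank_bins", "body_bins")]) + geo["flank_bins"]))
  prof <- rowMeans(matrix(per_rep, ncol = length(matrices)))
  fb <- geo[["flank_bins"]]; bb <- geo[["body_bins"]]; bs <- geo[["bin_size"]]
  seg <- c(rep("upstream", fb), rep("body", bb), rep("downstream", fb))
  pos <- c(seq(-fb * bs + bs / 2, -bs / 2, by = bs),
           seq_len(bb) - 0.5,
           seq(bs / 2, fb * bs - bs / 2, by = bs))
  res <- tibble(bin = seq_along(prof), segment = seg, position = pos,
                value = prof)
  structure(res, class = c("metagene_profile", class(res)),
            flank_bins = fb, body_bins = bb, bin_size = bs,
            n_replicates = length(matrices))
}

#' Readthrough index: downstream-of-poly(A) signal over gene-body signal
#'
#' Quantifies a transcription termination defect as the mean signal in the
#' `downstream_window_bp` window past the poly(A) site divided by the mean
#' gene-body signal (TSS + `body_excl_bp` to the poly(A) site, excluding
#' the pause region). Strand-aware; `NA` when the body mean is zero.
#'
#' @param track A `coverage_track`.
#' @param genes A `gene_annotation` or genes tibble.
#' @param downstream_window_bp Window length past the poly(A) site, bp.
#' @param body_excl_bp Bases excluded at the TSS end of the body.
#' @param strand_specific Match track strand to gene strand.
#' @return Tibble `gene_id`, `body_mean`, `downstream_mean`, `index`.
#' @export
readthrough_index <- function(track, genes, downstream_window_bp = 2000L,
                              body_excl_bp = 500L, strand_specific = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  if (downstream_window_bp <= 0L) abort("`downstream_window_bp` must be positive.")
  g <- if (inherits(genes, "gene_annotation")) genes$genes else as_tibble(genes)
  res <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    if (r$end <= r$start) {
      abort(paste0("Gene ", r$gene_id, " has a zero-length body window."))
    }
    # Short genes (e.g. histone genes) keep at least half their body.
    excl <- min(body_excl_bp, (r$end - r$start) %/% 2L)
    strand <- if (strand_specific) r$strand else "*"
    if (r$strand == "+") {
      body <- track_window(track, r$chrom, r$start + excl, r$end, strand)
      down <- track_window(track, r$chrom, r$end,
                           r$end + downstream_window_bp, strand)
    } else {
      body <- track_window(track, r$chrom, r$start, r$end - excl, strand)
      down <- track_window(track, r$chrom, r$start - downstream_window_bp,
                           r$start, strand)
    }
    bm <- mean(body); dm <- mean(down)
    res[[i]] <- tibble(gene_id = r$gene_id, body_mean = bm,
                       downstream_mean = dm,
                       index = if (bm > 0) dm / bm else NA_real_)
  }
  bind_rows(res)
}
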