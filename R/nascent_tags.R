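# Single-nucleotide polymerase-position tags from paired mNET-seq alignments.

#' Keep only properly paired, fully mapped read pairs
#'
#' Mirrors `samtools view -f 3`: a pair survives iff both mates are mapped
#' and the proper-pair flag is set. Input order is preserved.
#'
#' @param pairs A pairs tibble (see [read_alignment_pairs()]).
#' @return The filtered pairs tibble.
#' @export
filter_proper_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  filter(pairs, .data$proper & .data$mapped1 & .data$mapped2)
}

#' Extract single-nucleotide polymerase positions from read pairs
#'
#' The polymerase position of a pair is the reference coordinate of mate 2's
#' 3'-terminal *aligned* base: for a forward-oriented mate 2 the last
#' reference base consumed by its CIGAR (leftmost position plus the summed
#' M/D/N/=/X widths, minus one); for a reverse-oriented mate 2 its leftmost
#' aligned base. Soft clips never move the 3' position (clipped bases are
#' not aligned). The tag strand is mate 1's alignment orientation, inverted
#' when `flip_strand = TRUE` for library chemistries in which mate 1 is the
#' antisense read (the package's own simulator is such a chemistry).
#'
#' `tag_from_pair()` is the single-pair form of the same rule.
#'
#' @param pairs A pairs tibble that passed [filter_proper_pairs()].
#' @param flip_strand Invert mate 1's orientation when assigning tag strand.
#' @return A tibble of tags: `chrom`, `pos` (0-based single nucleotide),
#'   `strand`, `pair_id`.
#' @examples
#' p <- tibble::tibble(pair_id = "p1", chrom = "chr1",
#'                     start1 = 50L, cigar1 = "36M", strand1 = "+",
#'                     start2 = 100L, cigar2 = "36M", strand2 = "-",
#'                     proper = TRUE, mapped1 = TRUE, mapped2 = TRUE)
#' tags_from_pairs(p)
#' @export
tags_from_pairs <- function(pairs, flip_strand = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  strand = character(), pair_id = character()))
  }
  ref_w <- cigar_reference_width(pairs$cigar2)
  if (any(ref_w == 0L)) {
    abort(paste0("Mate-2 CIGAR consumes no reference bases for pair(s): ",
                 paste(utils::head(pairs$pair_id[ref_w == 0L], 5L),
                       collapse = ", ")))
  }
  pos <- ifelse(pairs$strand2 == "+",
                pairs$start2 + ref_w - 1L,
                pairs$start2)
  strand <- pairs$strand1
  if (flip_strand) strand <- ifelse(strand == "+", "-", "+")
  tibble(chrom = pairs$chrom, pos = as.integer(pos),
         strand = strand, pair_id = pairs$pair_id)
}

#' @rdname tags_from_pairs
#' @param pair A single-row pairs tibble (or a list with the same fields).
#' @export
tag_from_pair <- function(pair, flip_strand = FALSE) {
  tags_from_pairs(as_tibble(pair), flip_strand = flip_strand)
}

#' Bin polymerase tags into strand-specific coverage
#'
#' Counts tags per fixed-width bin per strand and optionally converts
#' counts to RPKM: `count / (bin_length_kb * library_size_millions)`, the
#' normalisation used for single-nucleotide coverage tracks. The track is
#' stored sparsely (only non-empty bins); `chrom_sizes` fixes each
#' chromosome's bin grid.
#'
#' @param tags Tag tibble from [tags_from_pairs()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 1, single-nucleotide).
#' @param normalize `"none"` (raw counts) or `"RPKM"`.
#' @param library_size Total mapped tags for RPKM; defaults to `nrow(tags)`.
#' @return A `coverage_track`: a tibble (`chrom`, `strand`, `start`, `end`,
#'   `count`, `score`) with attributes `bin_size`, `normalization`,
#'   `library_size`, `chrom_sizes`.
#' @export
tags_to_coverage <- function(tags, chrom_sizes, bin_size = 1L,
                             normalize = c("none", "RPKM"),
                             library_size = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(tags), bin_size >= 1L,
            !is.null(names(chrom_sizes)))
  library_size <- library_size %||% nrow(tags)
  if (normalize == "RPKM" && library_size <= 0) {
    abort("`library_size` must be positive for RPKM normalization.")
  }
  if (nrow(tags) > 0L && !all(tags$chrom %in% names(chrom_sizes))) {
    abort("Tags found on chromosomes absent from `chrom_sizes`.")
  }
  bin_size <- as.integer(bin_size)
  if (nrow(tags) == 0L) {
    tab <- tibble(chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  count = integer(), score = numeric())
  } else {
    tab <- tags |>
      mutate(bin = .data$pos %/% bin_size) |>
      dplyr::count(.data$chrom, .data$strand, .data$bin, name = "count") |>
      mutate(start = .data$bin * bin_size,
             end = pmin(.data$start + bin_size,
                        unname(chrom_sizes[.data$chrom])),
             score = if (normalize == "RPKM") {
               .data$count / ((.data$end - .data$start) / 1000 *
                                library_size / 1e6)
             } else as.numeric(.data$count)) |>
      select("chrom", "strand", "start", "end", "count", "score") |>
      arrange(.data$chrom, .data$strand, .data$start)
  }
  structure(tab, class = c("coverage_track", class(tab)),
            bin_size = bin_size, normalization = normalize,
            library_size = library_size, chrom_sizes = chrom_sizes)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin", attr(x, "bin_size"), "bp,",
      attr(x, "normalization"), "normalized, library",
      attr(x, "library_size"), "tags\n")
  NextMethod()
}

# Dense per-base signal over [start, end) for one chrom/strand of a sparse
# track ("*" strand pools both). Positions outside the chromosome are zero.
track_window <- function(track, chrom, start, end, strand = "*") {
  stopifnot(inherits(track, "coverage_track"), end >= start)
  n <- end - start
  out <- numeric(n)
  if (n == 0L) return(out)
  sel <- track$chrom == chrom & track$end > start & track$start < end
  if (strand != "*") sel <- sel & track$strand == strand
  rows <- track[sel, , drop = FALSE]
  # bedGraph/bigwig semantics: a bin's value applies to every base it covers.
  if (nrow(rows) > 0L && all(rows$end - rows$start == 1L)) {
    idx <- rows$start - start + 1L
    if (anyDuplicated(idx) == 0L) {
      out[idx] <- out[idx] + rows$score
      return(out)
    }
  }
  for (i in seq_len(nrow(rows))) {
    a <- max(rows$start[i], start) - start + 1L
    b <- min(rows$end[i], end) - start
    out[a:b] <- out[a:b] + rows$score[i]
  }
  out
}

#' Write a strand's coverage as bedGraph
#'
#' One line per non-empty bin, 0-based half-open, suitable for conversion
#' to bigwig with standard tools.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param strand Which strand to export (`"+"`, `"-"`, or `"*"` for all
#'   rows).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = "+") {
  stopifnot(inherits(track, "coverage_track"))
  rows <- if (strand == "*") track else track[track$strand == strand, ]
  df <- tibble(chrom = rows$chrom, start = rows$start, end = rows$end,
               score = rows$score)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_sizes Chromosome lengths for the restored track.
#' @param bin_size,normalization,library_size Track metadata to attach.
#' @export
read_bedgraph <- function(path, chrom_sizes, strand = "+", bin_size = 1L,
                          normalization = "none", library_size = NA_real_) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                        col_types = "ciid", progress = FALSE)
  tab <- tibble(chrom = df$chrom, strand = strand,
                start = as.integer(df$start), end = as.integer(df$end),
                count = NA_integer_, score = df$score)
  structure(tab, class = c("coverage_track", class(tab)),
            bin_size = as.integer(bin_size), normalization = normalization,
            library_size = library_size, chrom_sizes = chrom_sizes)
}
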