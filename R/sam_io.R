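# SAM / GTF / count-table I/O.

#' Write simulated read pairs to a coordinate-sorted SAM file
#'
#' Emits a valid SAM 1.6 file (`@HD` with `SO:coordinate`, one `@SQ` line per
#' synthetic chromosome) with two records per pair. Flags encode pairing,
#' proper pairing, orientation and mate rank (0x1|0x2 on both mates, 0x40 on
#' exactly one). Bases are written as uniform placeholders (sequence-level
#' realism is out of scope for the generator).
#'
#' @param pairs A pairs tibble (see [simulate_netseq_pairs()]).
#' @param path Output path (`.sam`).
#' @param chrom_sizes Named integer vector of chromosome lengths, e.g.
#'   `annotation$chrom_sizes`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(pairs, path, chrom_sizes) {
  stopifnot(is.data.frame(pairs), length(chrom_sizes) >= 1L,
            !is.null(names(chrom_sizes)))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  if (nrow(pairs) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }

  bad <- !(pairs$chrom %in% names(chrom_sizes)) |
    is.na(pairs$start1) | is.na(pairs$start2) |
    pairs$start1 < 0L | pairs$start2 < 0L
  if (any(bad)) {
    abort(paste0("Invalid/unsortable pair record(s): ",
                 paste(utils::head(pairs$pair_id[bad], 5L), collapse = ", ")))
  }
  assert_valid_cigar(pairs$cigar1)
  assert_valid_cigar(pairs$cigar2)

  flag_of <- function(proper, rev, mate_rev, first) {
    1L + 2L * as.integer(proper) + 16L * as.integer(rev) +
      32L * as.integer(mate_rev) + if (first) 64L else 128L
  }
  ref_end1 <- pairs$start1 + cigar_reference_width(pairs$cigar1)
  ref_end2 <- pairs$start2 + cigar_reference_width(pairs$cigar2)
  span_lo <- pmin(pairs$start1, pairs$start2)
  span_hi <- pmax(ref_end1, ref_end2)
  tlen1 <- ifelse(pairs$start1 <= pairs$start2, span_hi - span_lo,
                  -(span_hi - span_lo))

  mate_rec <- function(first) {
    start <- if (first) pairs$start1 else pairs$start2
    cigar <- if (first) pairs$cigar1 else pairs$cigar2
    strand <- if (first) pairs$strand1 else pairs$strand2
    ostrand <- if (first) pairs$strand2 else pairs$strand1
    mstart <- if (first) pairs$start2 else pairs$start1
    qlen <- cigar_query_width(cigar)
    tibble(qname = pairs$pair_id,
           flag = flag_of(pairs$proper, strand == "-", ostrand == "-", first),
           rname = pairs$chrom, pos = start + 1L, mapq = 60L, cigar = cigar,
           rnext = "=", pnext = mstart + 1L,
           tlen = as.integer(if (first) tlen1 else -tlen1),
           seq = strrep("A", qlen), qual = strrep("I", qlen))
  }
  recs <- bind_rows(mate_rec(TRUE), mate_rec(FALSE)) |>
    arrange(factor(.data$rname, levels = names(chrom_sizes)), .data$pos)

  writeLines(header, path)
  readr::write_tsv(recs, path, col_names = FALSE, append = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read properly paired alignments from SAM/BAM into a pairs tibble
#'
#' SAM input is converted through htslib (`Rsamtools::asBam`) and read back
#' as one row per pair; secondary and supplementary alignments are excluded
#' so each sequenced molecule contributes one pair at most.
#'
#' @param path A `.sam` or `.bam` file.
#' @return A pairs tibble with 0-based `start1`/`start2`, CIGARs, per-mate
#'   orientation, `proper`/`mapped1`/`mapped2` flags and `gene_id` recovered
#'   from the read name when present (`NA` otherwise).
#' @export
read_alignment_pairs <- function(path) {
  if (!file.exists(path)) abort(paste0("Alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"), flag = flag)
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(b$qname) == 0L) return(empty_pairs())
  rec <- tibble(qname = b$qname, flag = b$flag,
                chrom = as.character(b$rname),
                pos = as.integer(b$pos) - 1L, cigar = b$cigar)
  rec <- mutate(rec,
                first = bitwAnd(.data$flag, 64L) > 0L,
                proper = bitwAnd(.data$flag, 2L) > 0L,
                mapped = bitwAnd(.data$flag, 4L) == 0L,
                strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+"))
  m1 <- filter(rec, .data$first)
  m2 <- filter(rec, !.data$first)
  pairs <- dplyr::inner_join(
    select(m1, "qname", chrom1 = "chrom", start1 = "pos", cigar1 = "cigar",
           strand1 = "strand", proper1 = "proper", mapped1 = "mapped"),
    select(m2, "qname", chrom2 = "chrom", start2 = "pos", cigar2 = "cigar",
           strand2 = "strand", proper2 = "proper", mapped2 = "mapped"),
    by = "qname")
  tibble(pair_id = pairs$qname,
         chrom = pairs$chrom1,
         start1 = pairs$start1, cigar1 = pairs$cigar1, strand1 = pairs$strand1,
         start2 = pairs$start2, cigar2 = pairs$cigar2, strand2 = pairs$strand2,
         proper = pairs$proper1 & pairs$proper2,
         mapped1 = pairs$mapped1, mapped2 = pairs$mapped2,
         gene_id = ifelse(grepl("^G\\d+:", pairs$qname),
                          sub(":.*$", "", pairs$qname), NA_character_))
}

#' Read chromosome sizes from a SAM/BAM header
#'
#' @param path A `.sam` or `.bam` file.
#' @return Named integer vector of reference lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    lines <- readLines(path, n = 10000L)
    sq <- grep("^@SQ\t", lines, value = TRUE)
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    return(setNames(ln, sn))
  }
  h <- Rsamtools::scanBamHeader(path)[[1]]$targets
  setNames(as.integer(h), names(h))
}

#' Write / read a gene annotation as GTF
#'
#' Gene, transcript and exon features are emitted with `gene_id`,
#' `transcript_id`, `gene_class` and `exon_number` attributes; coordinates
#' convert between the package's 0-based half-open convention and GTF's
#' 1-based inclusive one at this boundary.
#'
#' @param annotation A `gene_annotation`.
#' @param path GTF file path.
#' @param chrom_sizes For `read_annotation_gtf()`: optional named vector of
#'   chromosome lengths; when `NULL`, sizes default to the rightmost feature
#'   end plus a 10 kb margin.
#' @return `write_annotation_gtf()` returns `path` invisibly;
#'   `read_annotation_gtf()` returns a `gene_annotation`.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  feat <- function(df, type, extra) {
    if (nrow(df) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = type, extra)
    gr
  }
  grs <- list(
    feat(g, "gene", S4Vectors::DataFrame(gene_id = g$gene_id,
                                         gene_class = g$class)),
    feat(g, "transcript", S4Vectors::DataFrame(gene_id = g$gene_id,
                                               transcript_id = g$transcript_id,
                                               gene_class = g$class)),
    feat(e, "exon", S4Vectors::DataFrame(gene_id = e$gene_id,
                                         transcript_id = e$transcript_id,
                                         exon_number = e$exon_rank)))
  grs <- grs[!vapply(grs, is.null, logical(1))]
  gr <- if (length(grs)) do.call(c, unname(grs)) else GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gdf <- filter(df, .data$type == "gene")
  tdf <- filter(df, .data$type == "transcript")
  edf <- filter(df, .data$type == "exon")
  genes <- tibble(
    gene_id = gdf$gene_id,
    transcript_id = tdf$transcript_id[match(gdf$gene_id, tdf$gene_id)],
    chrom = gdf$seqnames, strand = gdf$strand,
    start = as.integer(gdf$start - 1L), end = as.integer(gdf$end),
    class = if ("gene_class" %in% names(gdf)) gdf$gene_class else NA_character_)
  exons <- tibble(
    gene_id = edf$gene_id, transcript_id = edf$transcript_id,
    chrom = edf$seqnames, strand = edf$strand,
    start = as.integer(edf$start - 1L), end = as.integer(edf$end),
    exon_rank = as.integer(edf$exon_number))
  n_ex <- dplyr::count(exons, .data$gene_id)
  genes$n_exons <- n_ex$n[match(genes$gene_id, n_ex$gene_id)]
  genes <- arrange(genes, .data$chrom, .data$start)
  exons <- arrange(exons, .data$chrom, .data$start)
  if (is.null(chrom_sizes)) {
    mx <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- setNames(as.integer(mx + 10000L), names(mx))
  }
  new_gene_annotation(genes, exons, chrom_sizes)
}
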