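# Transcription-unit set construction: most-expressed isoform, expression
# filter, three-way gene classification, internal exons.

counts_matrix <- function(counts, id_col) {
  if (!id_col %in% names(counts)) {
    abort(paste0("Count table must have a `", id_col, "` column."))
  }
  num <- counts[vapply(counts, is.numeric, logical(1))]
  if (ncol(num) == 0L) abort("Count table has no replicate columns.")
  if (any(unlist(num) < 0, na.rm = TRUE)) abort("Counts must be non-negative.")
  num
}

#' Select the most expressed isoform of each gene
#'
#' Keeps, per gene, the transcript with the greatest count summed across
#' replicate columns. Ties are broken deterministically by lexicographically
#' smallest `transcript_id` and flagged. Genes with no counted transcript
#' are omitted (with a message).
#'
#' @param counts Tibble with a `transcript_id` column and one numeric column
#'   per replicate.
#' @param annotation A `gene_annotation`, or any tibble with
#'   `transcript_id` and `gene_id` columns mapping transcripts to genes.
#' @return Tibble `gene_id`, `transcript_id`, `total_count`, `tie`.
#' @export
select_top_isoform <- function(counts, annotation) {
  tx2gene <- if (inherits(annotation, "gene_annotation")) {
    distinct(annotation$exons, .data$transcript_id, .data$gene_id)
  } else {
    distinct(as_tibble(annotation), .data$transcript_id, .data$gene_id)
  }
  num <- counts_matrix(counts, "transcript_id")
  missing_tx <- setdiff(counts$transcript_id, tx2gene$transcript_id)
  if (length(missing_tx)) {
    abort(paste0("Counted transcript(s) absent from annotation: ",
                 paste(utils::head(missing_tx, 5L), collapse = ", ")))
  }
  tab <- tibble(transcript_id = counts$transcript_id,
                total_count = rowSums(num)) |>
    left_join(tx2gene, by = "transcript_id")
  sel <- tab |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$total_count), .data$transcript_id,
            .by_group = TRUE) |>
    summarise(tie = sum(.data$total_count == max(.data$total_count)) > 1L,
              transcript_id = .data$transcript_id[1],
              total_count = .data$total_count[1]) |>
    ungroup()
  uncounted <- setdiff(tx2gene$gene_id, sel$gene_id)
  if (length(uncounted)) {
    message(length(uncounted), " gene(s) had no counted transcript and were omitted.")
  }
  select(sel, "gene_id", "transcript_id", "total_count", "tie")
}

#' Flag expressed genes from replicate counts
#'
#' A row is kept iff its count is strictly greater than `min_reads` in at
#' least `min_replicates` replicate columns (the "more than 10 reads in two
#' biological replicates" rule).
#'
#' @param counts Tibble with an id column (`gene_id` or `transcript_id`)
#'   and one numeric column per replicate (at least `min_replicates`).
#' @param min_reads Strict lower bound on the per-replicate count.
#' @param min_replicates Number of replicates that must pass.
#' @return The input tibble with `n_pass` and `kept` columns appended.
#' @export
filter_expressed <- function(counts, min_reads = 10, min_replicates = 2) {
  id_col <- intersect(c("gene_id", "transcript_id"), names(counts))[1]
  if (is.na(id_col)) abort("Count table needs a `gene_id` or `transcript_id` column.")
  num <- counts_matrix(counts, id_col)
  if (ncol(num) < min_replicates) {
    abort(paste0("Count table has ", ncol(num), " replicate column(s); ",
                 min_replicates, " required."))
  }
  n_pass <- rowSums(num > min_reads)
  mutate(as_tibble(counts), n_pass = as.integer(n_pass),
         kept = n_pass >= min_replicates)
}

#' Classify genes as intron-containing, intronless or histone
#'
#' Histone identity (a curated, user-supplied id list) takes precedence over
#' exon structure; remaining single-exon genes are intronless; remaining
#' multi-exon genes are intron-containing. When `apply_length_cap` is set,
#' intron-containing genes whose genomic span exceeds the longest intronless
#' gene are labelled `unclassified` and thereby excluded from class
#' comparisons -- the cap makes class length distributions comparable.
#'
#' The operation is idempotent: labels are recomputed from structure alone.
#'
#' @param genes A `gene_annotation` or a genes tibble with `gene_id`,
#'   `start`, `end` and `n_exons` columns.
#' @param histone_ids Character vector of histone gene ids (must be a subset
#'   of the annotation's gene ids).
#' @param apply_length_cap Apply the longest-intronless-gene size cap.
#' @return The genes tibble with its `class` column (re)assigned.
#' @export
classify_genes <- function(genes, histone_ids = character(),
                           apply_length_cap = TRUE) {
  g <- if (inherits(genes, "gene_annotation")) genes$genes else as_tibble(genes)
  stopifnot(all(c("gene_id", "start", "end", "n_exons") %in% names(g)))
  unknown <- setdiff(histone_ids, g$gene_id)
  if (length(unknown)) {
    abort(paste0("histone_ids not present in annotation: ",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  cls <- ifelse(g$gene_id %in% histone_ids, "histone",
                ifelse(g$n_exons <= 1L, "intronless", "intron_containing"))
  if (apply_length_cap) {
    intronless_len <- (g$end - g$start)[cls == "intronless"]
    if (length(intronless_len) == 0L) {
      abort("Length cap requested but no intronless gene exists to define it.")
    }
    cap <- max(intronless_len)
    cls[cls == "intron_containing" & (g$end - g$start) > cap] <- "unclassified"
  }
  g$class <- cls
  g
}

#' Internal exons of each transcript
#'
#' Drops the genomically first and last exon of every transcript, keeping
#' only internal exons; transcripts with two or fewer exons contribute
#' nothing.
#'
#' @param exons Exon tibble (`transcript_id`, `chrom`, `start`, `end`, ...).
#' @return The exon tibble restricted to internal exons.
#' @export
internal_exons <- function(exons) {
  exons <- as_tibble(exons)
  if (nrow(exons) == 0L) return(exons)
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    filter(n() > 2L, row_number() > 1L, row_number() < n()) |>
    ungroup()
}

#' Write genomic intervals as a BED file
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   optional `strand` and a name column (`gene_id` or `transcript_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name_col <- intersect(c("gene_id", "transcript_id"), names(regions))[1]
  df <- tibble(chrom = regions$chrom,
               start = regions$start,
               end = regions$end,
               name = if (!is.na(name_col)) regions[[name_col]] else ".",
               score = 0L,
               strand = if ("strand" %in% names(regions)) regions$strand else ".")
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
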