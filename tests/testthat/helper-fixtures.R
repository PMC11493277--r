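# Shared fixtures: small configs, toy pair builders, and an independent
# brute-force CIGAR walker used as the oracle for 3'-end extraction.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_genes = c(intron_containing = 3L, intronless = 2L,
                         histone = 1L),
             depth = 2000, ...)
}

# Build a one-row pairs tibble with sensible defaults.
toy_pair <- function(pair_id = "p1", chrom = "chr1",
                     start1 = 0L, cigar1 = "36M", strand1 = "+",
                     start2 = 100L, cigar2 = "36M", strand2 = "-",
                     proper = TRUE, mapped1 = TRUE, mapped2 = TRUE) {
  tibble::tibble(pair_id = pair_id, chrom = chrom,
                 start1 = as.integer(start1), cigar1 = cigar1,
                 strand1 = strand1,
                 start2 = as.integer(start2), cigar2 = cigar2,
                 strand2 = strand2,
                 proper = proper, mapped1 = mapped1, mapped2 = mapped2,
                 gene_id = NA_character_)
}

# Brute-force oracle: walk the CIGAR one operation at a time, advancing a
# reference cursor for M/D/N/=/X only, and return the 3'-terminal aligned
# base (forward: last consumed base; reverse: leftmost aligned base).
oracle_tag_pos <- function(start, cigar, orientation) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  cursor <- start
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    code <- sub("^[0-9]+", "", op)
    if (code %in% c("M", "D", "N", "=", "X")) cursor <- cursor + n
  }
  if (orientation == "+") cursor - 1L else start
}

# Random syntactically valid CIGAR with >= 1 reference-consuming op and a
# query-consuming structure (clips only at the ends, as in real alignments).
random_cigar <- function() {
  n_core <- sample(1:5, 1)
  core_ops <- character(0)
  prev_skip <- TRUE
  for (i in seq_len(n_core)) {
    # alternate M-ish blocks with I/D/N so ops stay structurally valid
    op <- if (prev_skip) "M" else sample(c("I", "D", "N", "M"), 1)
    prev_skip <- op %in% c("I", "D", "N")
    core_ops <- c(core_ops, paste0(sample(1:200, 1), op))
  }
  if (!grepl("M", core_ops[length(core_ops)])) {
    core_ops <- c(core_ops, paste0(sample(1:200, 1), "M"))
  }
  lead <- if (runif(1) < 0.3) paste0(sample(1:20, 1), "S") else ""
  trail <- if (runif(1) < 0.3) paste0(sample(1:20, 1), "S") else ""
  paste0(lead, paste0(core_ops, collapse = ""), trail)
}

# Dense per-base vector of a whole chromosome from a sparse track (test-side
# re-implementation used to cross-check window extraction).
dense_signal <- function(track, chrom, len, strand = "+") {
  out <- numeric(len)
  rows <- track[track$chrom == chrom & track$strand == strand, ]
  for (i in seq_len(nrow(rows))) {
    out[(rows$start[i] + 1):rows$end[i]] <-
      out[(rows$start[i] + 1):rows$end[i]] + rows$score[i]
  }
  out
}
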