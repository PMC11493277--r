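# Shared internal helpers.
#
# Coordinates are 0-based half-open [start, end) everywhere inside the
# package; SAM/GTF (1-based inclusive) and bedGraph/BED (0-based half-open)
# are converted at the I/O boundary only.

# Run `code` under a dedicated RNG stream so that adding one simulation stage
# never perturbs the draws of another. Each operation gets a fixed offset
# from the config seed.
with_op_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), is.numeric(offset))
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}

OP_SEED_ANNOTATION <- 101L
OP_SEED_RNASEQ     <- 202L
OP_SEED_NETSEQ     <- 303L

cigar_op_pattern <- "^([0-9]+[MIDNSHP=X])+$"

assert_valid_cigar <- function(cigar) {
  bad <- is.na(cigar) | !grepl(cigar_op_pattern, cigar)
  if (any(bad)) {
    abort(paste0("Malformed CIGAR string(s): ",
                 paste(utils::head(unique(cigar[bad]), 5L), collapse = ", ")))
  }
  invisible(cigar)
}

# Reference bases consumed by a CIGAR (M, D, N, =, X per the SAM spec).
cigar_reference_width <- function(cigar) {
  assert_valid_cigar(cigar)
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# Query bases consumed (M, I, S, =, X).
cigar_query_width <- function(cigar) {
  assert_valid_cigar(cigar)
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# Mean of `x` (one value per source bin of equal width) resampled to `n_out`
# equal-width bins by exact length-weighted averaging. Works on the cumulative
# integral with linear interpolation at fractional cut points, so a constant
# input maps to a constant output and total mass is preserved.
resample_mean <- function(x, n_out) {
  if (n_out <= 0) abort("`n_out` must be a positive integer.")
  n_in <- length(x)
  if (n_in == 0L) return(rep(NA_real_, n_out))
  if (n_in == n_out) return(as.numeric(x))
  cum <- c(0, cumsum(as.numeric(x)))          # integral in bin units
  cuts <- seq(0, n_in, length.out = n_out + 1L)
  cum_at <- function(p) {
    i <- pmin(floor(p), n_in - 1L)
    cum[i + 1L] + (p - i) * x[i + 1L]
  }
  vals <- cum_at(cuts)
  diff(vals) / diff(cuts)
}

# sample() treats a length-1 vector as 1:x; this draws from the vector as-is.
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

`%0%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
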