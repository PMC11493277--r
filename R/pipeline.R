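# End-to-end orchestration: simulate -> extract -> quantify -> profile ->
# report, with a manifest for reproducibility.

#' Run the full simulation stage
#'
#' Generates the annotation, the RNA-seq library (known per-gene intron
#' retention) and one mNET-seq library per condition, then writes
#' everything (GTF, SAM, truth JSON) plus a manifest recording the seed
#' and parameters from which every output is re-derivable. Identical
#' configs produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if needed).
#' @param conditions Named numeric vector of mNET-seq conditions mapping
#'   condition label to readthrough gain; treated conditions may also scale
#'   pausing/body via `treated_pause_scale` / `treated_body_scale`.
#' @param treated_pause_scale,treated_body_scale Multipliers applied to
#'   `pause_height` / `body_density` for every non-control condition
#'   (transcription-downregulating treatments lower both).
#' @return Invisibly, a list of written paths.
#' @export
run_simulate <- function(config, out_dir,
                         conditions = c(control = 1,
                                        treated = config$readthrough_gain),
                         treated_pause_scale = 0.5,
                         treated_body_scale = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be a named vector: label -> readthrough gain.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (sum(config$n_genes) == 0L) {
    warn("No genes requested; outputs will be header-only.")
  }

  sim <- simulate_annotation(config)
  ann <- sim$annotation
  truth <- sim$truth

  rna <- simulate_rnaseq_pairs(ann, truth, config)
  truth <- rna$truth

  paths <- list(
    annotation = file.path(out_dir, "annotation.gtf"),
    rnaseq = file.path(out_dir, "rnaseq.sam"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_annotation_gtf(ann, paths$annotation)
  write_alignments(rna$pairs, paths$rnaseq, ann$chrom_sizes)

  for (cond in names(conditions)) {
    is_control <- cond == "control"
    net <- simulate_netseq_pairs(
      ann, truth, config, condition = cond,
      readthrough_gain = unname(conditions[[cond]]),
      pause_height = config$pause_height *
        (if (is_control) 1 else treated_pause_scale),
      body_density = config$body_density *
        (if (is_control) 1 else treated_body_scale))
    truth <- net$truth
    p <- file.path(out_dir, paste0("netseq_", cond, ".sam"))
    write_alignments(net$pairs, p, ann$chrom_sizes)
    paths[[paste0("netseq_", cond)]] <- p
  }
  write_truth_json(truth, paths$truth)

  manifest <- list(
    package = "nascentr",
    version = as.character(utils::packageVersion("nascentr")),
    seed = config$seed,
    config = unclass(config),
    conditions = as.list(conditions),
    treated_pause_scale = treated_pause_scale,
    treated_body_scale = treated_body_scale,
    chrom_sizes = as.list(ann$chrom_sizes),
    # mate1 is the antisense read in the simulated chemistry, so tag
    # extraction must flip mate1's orientation to get transcript strand
    flip_strand = TRUE,
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Run the full analysis stage on a simulation bundle
#'
#' Reads the manifest, annotation and alignments produced by
#' [run_simulate()]; extracts single-nucleotide tags and strand-specific
#' RPKM coverage for every mNET-seq condition (writing bedGraphs);
#' computes per-gene splicing efficiency from the RNA-seq library; builds
#' scaled metagene profiles and per-gene readthrough indices per
#' condition; and writes TSV tables plus a JSON summary (per-class mean
#' efficiency, median readthrough index per condition, rank-test p-value
#' treated vs control readthrough).
#'
#' @param sim_dir Directory written by [run_simulate()].
#' @param out_dir Output directory (created if needed; defaults to
#'   `sim_dir`).
#' @param flank_bp,body_bins,bin_size Metagene geometry.
#' @param downstream_window_bp,body_excl_bp Readthrough-index windows.
#' @return Invisibly, the summary list.
#' @export
run_analysis <- function(sim_dir, out_dir = sim_dir,
                         flank_bp = 2000L, body_bins = 100L, bin_size = 10L,
                         downstream_window_bp = 2000L, body_excl_bp = 500L) {
  manifest_path <- file.path(sim_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("Missing input: ", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom_sizes <- unlist(manifest$chrom_sizes)
  flip <- isTRUE(manifest$flip_strand)

  ann_path <- file.path(sim_dir, "annotation.gtf")
  for (p in c(ann_path, file.path(sim_dir, "rnaseq.sam"))) {
    if (!file.exists(p)) abort(paste0("Missing input: ", p))
  }
  ann <- read_annotation_gtf(ann_path, chrom_sizes = chrom_sizes)
  genes <- ann$genes

  # Splicing efficiency from RNA-seq.
  rna_pairs <- read_alignment_pairs(file.path(sim_dir, "rnaseq.sam"))
  splicing <- gene_splicing_efficiency(rna_pairs, ann)
  splicing <- left_join(splicing, select(genes, "gene_id", "class"),
                        by = "gene_id")
  readr::write_tsv(splicing, file.path(out_dir, "splicing_efficiency.tsv"),
                   progress = FALSE)

  conds <- names(manifest$conditions)
  profiles <- list()
  rt <- list()
  for (cond in conds) {
    sam <- file.path(sim_dir, paste0("netseq_", cond, ".sam"))
    if (!file.exists(sam)) abort(paste0("Missing input: ", sam))
    pairs <- filter_proper_pairs(read_alignment_pairs(sam))
    tags <- tags_from_pairs(pairs, flip_strand = flip)
    track <- tags_to_coverage(tags, chrom_sizes, bin_size = 1L,
                              normalize = "RPKM")
    for (s in c("+", "-")) {
      write_bedgraph(track, file.path(
        out_dir, paste0("netseq_", cond, if (s == "+") ".fwd" else ".rev",
                        ".bedgraph")), strand = s)
    }
    mg_genes <- filter(genes, .data$class != "unclassified" | is.na(.data$class))
    mat <- scale_regions_matrix(track, mg_genes, flank_bp = flank_bp,
                                body_bins = body_bins, bin_size = bin_size)
    profiles[[cond]] <- mean_profile(mat)
    readr::write_tsv(as_tibble(profiles[[cond]]),
                     file.path(out_dir, paste0("profile_", cond, ".tsv")),
                     progress = FALSE)
    rt[[cond]] <- readthrough_index(
      track, mg_genes, downstream_window_bp = downstream_window_bp,
      body_excl_bp = body_excl_bp) |>
      mutate(condition = cond)
  }
  rt_tab <- bind_rows(rt)
  readr::write_tsv(rt_tab, file.path(out_dir, "readthrough_index.tsv"),
                   progress = FALSE)

  class_eff <- splicing |>
    filter(!is.na(.data$efficiency)) |>
    group_by(.data$class) |>
    summarise(mean_efficiency = mean(.data$efficiency), n = n())

  rt_p <- NA_real_
  if (all(c("control", "treated") %in% conds)) {
    a <- filter(rt_tab, .data$condition == "treated", !is.na(.data$index))$index
    b <- filter(rt_tab, .data$condition == "control", !is.na(.data$index))$index
    if (length(a) >= 2L && length(b) >= 2L) {
      rt_p <- suppressWarnings(wilcox.test(a, b)$p.value)
    }
  }
  summary <- list(
    inputs = list(sim_dir = sim_dir, manifest = manifest_path),
    parameters = list(flank_bp = flank_bp, body_bins = body_bins,
                      bin_size = bin_size,
                      downstream_window_bp = downstream_window_bp,
                      body_excl_bp = body_excl_bp, flip_strand = flip),
    class_mean_efficiency = class_eff,
    readthrough_median = lapply(
      setNames(conds, conds),
      function(cc) stats::median(rt_tab$index[rt_tab$condition == cc],
                                 na.rm = TRUE)),
    readthrough_rank_sum_p = rt_p)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summary)
}
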