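# ggplot2 views of the result objects.

#' Plot a metagene profile
#'
#' Signal per bin across the scaled gene (upstream flank, scaled body,
#' downstream flank), the standard way termination defects and pausing
#' changes are visualised.
#'
#' @param object A `metagene_profile` from [mean_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  fb <- attr(object, "flank_bins")
  bb <- attr(object, "body_bins")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(fb + 0.5, fb + bb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, fb + 0.5, fb + bb + 0.5, 2 * fb + bb),
      labels = c("-flank", "TSS", "pA", "+flank")) +
    ggplot2::labs(x = NULL, y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Compare metagene profiles across conditions
#'
#' @param profiles Named list of `metagene_profile` objects (one per
#'   condition).
#' @return A ggplot object with one line per condition.
#' @export
plot_profiles <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  df <- purrr::imap(profiles, function(p, nm) {
    mutate(as_tibble(p), condition = nm)
  }) |> bind_rows()
  fb <- attr(profiles[[1]], "flank_bins")
  bb <- attr(profiles[[1]], "body_bins")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(fb + 0.5, fb + bb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, fb + 0.5, fb + bb + 0.5, 2 * fb + bb),
      labels = c("-flank", "TSS", "pA", "+flank")) +
    ggplot2::labs(x = NULL, y = "mean signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a coverage track window
#'
#' @param object A `coverage_track`.
#' @param chrom,start,end Window to display (0-based half-open); default
#'   the whole recorded extent.
#' @param ... Unused.
#' @return A ggplot object, one facet per strand.
#' @export
autoplot.coverage_track <- function(object, chrom = NULL, start = NULL,
                                    end = NULL, ...) {
  df <- as_tibble(object)
  chrom <- chrom %||% df$chrom[1]
  df <- filter(df, .data$chrom == !!chrom)
  if (!is.null(start)) df <- filter(df, .data$end > !!start)
  if (!is.null(end)) df <- filter(df, .data$start < !!end)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strand)) +
    ggplot2::labs(x = paste0(chrom, " (bp)"),
                  y = attr(object, "normalization")) +
    ggplot2::theme_minimal()
}
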