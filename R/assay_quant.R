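# Bench-assay arithmetic: ChIP %input, delta-delta-Ct, western ratios,
# differential-expression significance calls.

#' ChIP-qPCR signal as percent of input with IgG background removal
#'
#' `100 * max(ip - igg, 0) / (input / input_dilution)`. The IgG-subtracted
#' signal is clamped at zero (percent input is a proportion); rows where
#' the clamp fires are flagged. The input quantity is corrected for its
#' dilution (default 1/10) before use. The result is invariant under a
#' common rescaling of all three quantities.
#'
#' @param data Tibble with `ip_quantity`, `igg_quantity`, `input_quantity`
#'   columns (same qPCR-derived units, non-negative).
#' @param input_dilution Fraction of input carried into the qPCR (0, 1].
#' @return The tibble with `percent_input` and `clamped` columns appended.
#' @examples
#' chip_percent_input(tibble::tibble(ip_quantity = 25, igg_quantity = 5,
#'                                   input_quantity = 100))
#' @export
chip_percent_input <- function(data, input_dilution = 0.1) {
  data <- as_tibble(data)
  stopifnot(all(c("ip_quantity", "igg_quantity", "input_quantity") %in%
                  names(data)))
  if (input_dilution <= 0 || input_dilution > 1) {
    abort("`input_dilution` must lie in (0, 1].")
  }
  if (any(data$ip_quantity < 0 | data$igg_quantity < 0 |
            data$input_quantity < 0)) {
    abort("qPCR quantities must be non-negative.")
  }
  if (any(data$input_quantity == 0)) abort("`input_quantity` must be positive.")
  bg <- data$ip_quantity - data$igg_quantity
  mutate(data,
         clamped = bg < 0,
         percent_input = 100 * pmax(bg, 0) /
           (data$input_quantity / input_dilution))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `efficiency^-ddCt` with
#' `ddCt = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control`;
#' values are fold changes of the target, normalised to the reference gene
#' and shown relative to the control condition.
#'
#' @param data Tibble with `ct_target_treated`, `ct_ref_treated`,
#'   `ct_target_control`, `ct_ref_control` columns (finite Ct values).
#' @param efficiency Amplification efficiency per cycle (> 1; 2 = perfect
#'   doubling).
#' @return The tibble with a `fold_change` column appended.
#' @examples
#' relative_expression(tibble::tibble(
#'   ct_target_treated = 20, ct_ref_treated = 10,
#'   ct_target_control = 21, ct_ref_control = 10))
#' @export
relative_expression <- function(data, efficiency = 2) {
  data <- as_tibble(data)
  need <- c("ct_target_treated", "ct_ref_treated",
            "ct_target_control", "ct_ref_control")
  stopifnot(all(need %in% names(data)))
  if (efficiency <= 1) abort("`efficiency` must exceed 1.")
  if (any(!is.finite(as.matrix(data[need])))) abort("Ct values must be finite.")
  ddct <- (data$ct_target_treated - data$ct_ref_treated) -
    (data$ct_target_control - data$ct_ref_control)
  mutate(data, fold_change = efficiency^(-ddct))
}

#' Western-blot quantification ratio
#'
#' `(ip_treated / h3_treated) / (ip_dmso / h3_dmso)`: each
#' immunoprecipitated signal normalised to its histone H3 loading control,
#' then expressed relative to the vehicle (DMSO) condition.
#'
#' @param data Tibble with `ip_treated`, `h3_treated`, `ip_dmso`,
#'   `h3_dmso` columns (band intensities; denominators must be positive).
#' @return The tibble with a `ratio` column appended.
#' @examples
#' western_ratio(tibble::tibble(ip_treated = 2, h3_treated = 1,
#'                              ip_dmso = 1, h3_dmso = 1))
#' @export
western_ratio <- function(data) {
  data <- as_tibble(data)
  need <- c("ip_treated", "h3_treated", "ip_dmso", "h3_dmso")
  stopifnot(all(need %in% names(data)))
  if (any(data$h3_treated <= 0 | data$h3_dmso <= 0 | data$ip_dmso <= 0)) {
    abort("Denominator signals (h3_treated, h3_dmso, ip_dmso) must be positive.")
  }
  mutate(data, ratio = (data$ip_treated / data$h3_treated) /
           (data$ip_dmso / data$h3_dmso))
}

#' Differential-expression significance calls
#'
#' A gene is `up` iff `log2fc >= log2(fc_threshold)` and
#' `adj_p < p_threshold` (strict); `down` symmetrically; `ns` otherwise.
#' The three calls partition any table.
#'
#' @param data Tibble with `log2fc` and `adj_p` columns (`adj_p` in
#'   `[0, 1]`).
#' @param fc_threshold Fold-change threshold (default two-fold).
#' @param p_threshold Adjusted-p threshold (strict upper bound).
#' @return The tibble with a `status` factor (`up`/`down`/`ns`) appended.
#' @examples
#' de_significant(tibble::tibble(log2fc = c(1.5, 1.5, -0.9),
#'                               adj_p = c(0.01, 0.05, 0.001)))
#' @export
de_significant <- function(data, fc_threshold = 2, p_threshold = 0.05) {
  data <- as_tibble(data)
  stopifnot(all(c("log2fc", "adj_p") %in% names(data)))
  if (any(data$adj_p < 0 | data$adj_p > 1, na.rm = TRUE)) {
    abort("`adj_p` must lie in [0, 1].")
  }
  lt <- log2(fc_threshold)
  status <- dplyr::case_when(
    data$adj_p < p_threshold & data$log2fc >= lt ~ "up",
    data$adj_p < p_threshold & data$log2fc <= -lt ~ "down",
    TRUE ~ "ns")
  mutate(data, status = factor(status, levels = c("up", "down", "ns")))
}
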