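#' Truncated percentage ratio indices
#'
#' Craniodental ratio indices of the form `floor(100 * numerator /
#' denominator)`. Truncation, not rounding, is used: it is the only rule that
#' reproduces every printed palatal index of the *Titanotaria orangensis*
#' holotype (rounding fails on several rows, e.g. 12/61 prints 19, not 20).
#'
#' @param numerator,denominator Positive measurements in matching units.
#' @return Integer index (vectorised).
#' @export
truncated_percent_ratio <- function(numerator, denominator) {
  if (any(!is.finite(numerator) | numerator <= 0)) {
    stop("numerator must be positive", call. = FALSE)
  }
  if (any(!is.finite(denominator) | denominator <= 0)) {
    stop("denominator must be positive", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator))
}

#' Palatal measurements of the Titanotaria orangensis holotype
#'
#' The measurements (mm) behind the palate width index (C1 palate width over
#' M1 palate width) and the transverse palatal arch indices (palatal depth
#' over palatal width at each tooth position), with the index recomputed by
#' [truncated_percent_ratio()].
#'
#' @return A tibble: `index_name`, `position`, `numerator`, `denominator`,
#'   `index`.
#' @export
titanotaria_palatal_indices <- function() {
  x <- tibble::tribble(
    ~index_name,            ~position, ~numerator, ~denominator,
    "palate_width",         "C1/M1",   61,         87,
    "transverse_arch",      "C1",      12,         61,
    "transverse_arch",      "P1",      12,         53,
    "transverse_arch",      "P2",      14,         60,
    "transverse_arch",      "P3",      24,         67,
    "transverse_arch",      "P4",      26,         72,
    "transverse_arch",      "M1",      26,         87,
    "transverse_arch",      "M2",      22,         84
  )
  dplyr::mutate(x, index = truncated_percent_ratio(.data$numerator,
                                                   .data$denominator))
}
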