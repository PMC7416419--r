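#' Tidy a resemblance matrix into sample pairs
#'
#' @param x A [bray_curtis()] `resemblance` matrix.
#' @param ... Unused.
#' @return Tibble `sample_1`, `sample_2`, `similarity` (upper triangle).
#' @export
tidy.resemblance <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_1 = rownames(m)[idx[, 1]],
                 sample_2 = colnames(m)[idx[, 2]],
                 similarity = m[idx])
}

#' Tidy SIMPER contributions
#'
#' @param x A [simper_contrib()] result.
#' @param which `"between"` (default) or `"within"`.
#' @param ... Unused.
#' @return The requested contribution tibble.
#' @export
tidy.lake_simper <- function(x, which = c("between", "within"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Tidy dbRDA axis scores
#' @param x A [dbrda_fit()] result.
#' @param ... Unused.
#' @return Tibble of per-sample axis scores.
#' @export
tidy.lake_dbrda <- function(x, ...) x$scores

#' One-row dbRDA model summary
#' @param x A [dbrda_fit()] result.
#' @param ... Unused.
#' @return Tibble with adjusted R-squared, axis-1 percent fitted/total
#'   variation and the selected variables.
#' @export
glance.lake_dbrda <- function(x, ...) {
  tibble::tibble(
    adj_r_squared = x$adj_r_squared,
    axis1_pct_fitted = x$axes$pct_fitted[1],
    axis1_pct_total = x$axes$pct_total[1],
    pct_total_fitted = sum(x$axes$pct_total),
    n_variables = length(x$selected),
    variables = paste(x$selected, collapse = "+")
  )
}
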