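#' Heat map of relative abundance by sample
#'
#' Samples ordered by depth, then season; OTUs in the given (or current)
#' column order. The standard community-overview display for stratified
#' time series.
#'
#' @param table Abundance table (`sample_id` plus percent columns).
#' @param meta Sample metadata with `sample_id`, `depth_code`, `season`.
#' @return A ggplot object.
#' @export
plot_abundance_heatmap <- function(table, meta) {
  long <- table |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_name",
                        values_to = "ra") |>
    dplyr::inner_join(
      dplyr::select(meta, "sample_id", "depth_code", "season"),
      by = "sample_id") |>
    dplyr::mutate(
      depth_code = factor(.data$depth_code, levels = depth_codes()),
      otu_name = factor(.data$otu_name, levels = setdiff(names(table),
                                                         "sample_id")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$otu_name,
                                     y = .data$sample_id,
                                     fill = .data$ra)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$depth_code,
                                             .data$season),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "Relative\nabundance (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Seasonal alpha-diversity profile
#'
#' Simpson's index of diversity per sample, one line per filter fraction,
#' samples arranged by depth then date.
#'
#' @param diversity Output of [simpson_diversity()].
#' @param meta Sample metadata with `sample_id`, `date`, `depth_code`,
#'   `filter_fraction_um`, `season`.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(diversity, meta) {
  df <- diversity |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::mutate(depth_code = factor(.data$depth_code,
                                      levels = depth_codes()),
                  fraction = factor(.data$filter_fraction_um))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$simpson,
                                   colour = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$season), size = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$depth_code)) +
    ggplot2::labs(x = NULL, y = "Simpson's index of diversity",
                  colour = "Fraction (µm)") +
    ggplot2::theme_bw(base_size = 9)
}

#' Ordination plot for a dbRDA fit
#'
#' Axis-1/axis-2 sample scores with percent fitted and total variation in
#' the axis labels; points coloured by any metadata column joined on.
#'
#' @param object A [dbrda_fit()] result.
#' @param meta Optional sample metadata (`sample_id`, `season`,
#'   `depth_code`) for colour/shape.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lake_dbrda <- function(object, meta = NULL, ...) {
  sc <- object$scores
  ax <- names(sc)[2:min(3, ncol(sc))]
  lab <- function(i) sprintf("dbRDA%d (%.0f%% fitted, %.0f%% total)", i,
                             object$axes$pct_fitted[i],
                             object$axes$pct_total[i])
  if (length(ax) == 1) sc$.axis2 <- 0 else sc$.axis2 <- sc[[ax[2]]]
  if (!is.null(meta)) {
    sc <- dplyr::left_join(sc, meta, by = "sample_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[ax[1]]],
                                          y = .data$.axis2,
                                          colour = .data$season,
                                          shape = .data$depth_code))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[ax[1]]],
                                          y = .data$.axis2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1),
                  y = if (length(ax) > 1) lab(2) else NULL) +
    ggplot2::theme_bw(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
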