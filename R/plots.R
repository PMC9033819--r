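#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

grid_to_tibble <- function(grid) {
  v <- grid$values
  tibble::tibble(
    cell_row = rep(seq_len(nrow(v)), times = ncol(v)),
    cell_col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  ) |> dplyr::filter(!is.na(.data$value))
}

#' Plot a raster grid
#'
#' @param object An [eeq_grid].
#' @param ... Unused.
#' @return A ggplot; north is up (row 1 at the top).
#' @export
autoplot.eeq_grid <- function(object, ...) {
  df <- grid_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_col, .data$cell_row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a LISA cluster map
#'
#' @param object A `lisa_result` from [local_moran()].
#' @param ... Unused.
#' @return A ggplot of the unit lattice coloured by cluster label.
#' @export
autoplot.lisa_result <- function(object, ...) {
  stopifnot(all(c("urow", "ucol") %in% names(object)))
  cols <- c("H-H" = "#b2182b", "L-L" = "#2166ac", "H-L" = "#ef8a62",
            "L-H" = "#67a9cf", "not significant" = "grey85")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$ucol, .data$urow, fill = .data$cluster)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = cols, name = "LISA cluster") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Moran scatter plot
#'
#' Standardized unit values against their spatial lag; the slope of the
#' fitted line is the global Moran's I for row-standardized weights.
#'
#' @param lisa `lisa_result` from [local_moran()].
#' @return A ggplot.
#' @export
plot_moran_scatter <- function(lisa) {
  df <- tibble::as_tibble(lisa)
  ggplot2::ggplot(df, ggplot2::aes(.data$deviation, .data$lag,
                                   colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black",
                         linewidth = 0.5) +
    ggplot2::labs(x = "deviation from mean", y = "spatial lag") +
    ggplot2::theme_minimal()
}

#' Plot factor-detection q values
#'
#' @param factors Tibble with `indicator`, `q` (from [run_pipeline()]'s
#'   `factors` element or assembled from [factor_q()] results).
#' @return A ggplot bar chart ordered by q.
#' @export
plot_factor_q <- function(factors) {
  df <- dplyr::arrange(factors, .data$q)
  df$indicator <- factor(df$indicator, levels = df$indicator)
  ggplot2::ggplot(df, ggplot2::aes(.data$indicator, .data$q)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "q (share of variance explained)") +
    ggplot2::theme_minimal()
}
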