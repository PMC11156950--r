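# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of a gradient set
#'
#' @param object An `fcga_gradients`.
#' @param ... Unused.
#' @return A ggplot: explained variance ratio per gradient.
#' @export
autoplot.fcga_gradients <- function(object, ...) {
  d <- tibble::tibble(
    gradient = seq_along(object$explained_variance_ratio),
    explained_variance = object$explained_variance_ratio)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gradient,
                                  y = .data$explained_variance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "gradient", y = "explained variance ratio") +
    ggplot2::theme_minimal()
}

#' Map gradient coefficients back onto the toy cortex grid
#'
#' @param gs An `fcga_gradients` computed on a toy cortex.
#' @param cortex The `fcga_cortex` the time series came from.
#' @param components Which gradients to draw (default first two).
#' @return A ggplot of tile maps, one facet per gradient.
#' @export
plot_gradient_map <- function(gs, cortex, components = 1:2) {
  stopifnot(inherits(gs, "fcga_gradients"), inherits(cortex, "fcga_cortex"))
  if (nrow(gs$coefficients) != cortex$n) {
    abort_fcga("gradient set and cortex disagree on n_vertices",
               "fcga_argument_error")
  }
  components <- intersect(components, seq_len(ncol(gs$coefficients)))
  d <- tidy(gs) |>
    dplyr::filter(.data$gradient %in% components) |>
    dplyr::mutate(x = cortex$coords[.data$vertex, 1],
                  y = cortex$coords[.data$vertex, 2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~gradient, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Per-gradient spatial similarity profile
#'
#' @param object An `fcga_similarity`.
#' @param ... Unused.
#' @export
autoplot.fcga_similarity <- function(object, ...) {
  ggplot2::ggplot(object$per_gradient,
                  ggplot2::aes(x = .data$gradient, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_rho, linetype = "dashed") +
    ggplot2::labs(x = "gradient",
                  y = sprintf("Spearman rho (%s)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Distribution of per-repeat prediction performance
#'
#' @param object An `fcga_prediction`.
#' @param metric `"mae"` or `"r"`.
#' @param ... Unused.
#' @export
autoplot.fcga_prediction <- function(object, metric = c("mae", "r"), ...) {
  metric <- match.arg(metric)
  d <- tidyr::pivot_longer(object$per_repeat, cols = c("mae", "r"),
                           names_to = "metric", values_to = "value") |>
    dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Paired per-repeat MAE of the two feature constructions
#'
#' @param object An `fcga_comparison`.
#' @param ... Unused.
#' @export
autoplot.fcga_comparison <- function(object, ...) {
  d <- object$paired |>
    dplyr::select("repeat_index", "mae_g2p", "mae_p2g") |>
    tidyr::pivot_longer(cols = c("mae_g2p", "mae_p2g"),
                        names_to = "construction", values_to = "mae") |>
    dplyr::mutate(construction = dplyr::recode(
      .data$construction,
      mae_g2p = "gradients-to-parcellation",
      mae_p2g = "parcellation-to-gradients"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$construction, y = .data$mae)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "MAE per repeat") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
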