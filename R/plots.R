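## ggplot2 diagnostics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the CRF training objective trace
#'
#' @param object A `shape_crf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_crf <- function(object, ...) {
  df <- tibble(evaluation = seq_along(object$trace),
               objective = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$evaluation, .data$objective)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "objective evaluation",
                  y = "penalized negative log-likelihood",
                  title = "CRF training trace") +
    ggplot2::theme_minimal()
}

#' Plot per-class accuracy and SOV of an evaluation
#'
#' @param object A `shape_eval` from [evaluate_prediction()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_eval <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$state != "total", !is.na(.data$value)) |>
    dplyr::mutate(metric = paste0(.data$metric, .data$states))
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~states, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "shape state", y = "percent", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-residue posterior marginals
#'
#' Heatmap of the eight posterior state probabilities along the chain,
#' with the Viterbi path overlaid as points.
#'
#' @param prediction A per-residue prediction tibble
#'   (from [predict.shape_crf()] or [predict.shape_predictor()]).
#' @return A ggplot.
#' @export
plot_marginals <- function(prediction) {
  long <- prediction |>
    dplyr::select("num", "shape", dplyr::starts_with("P_")) |>
    tidyr::pivot_longer(dplyr::starts_with("P_"), names_to = "state",
                        values_to = "p") |>
    dplyr::mutate(state = factor(sub("^P_", "", .data$state),
                                 levels = rev(shape_states())))
  ggplot2::ggplot(long, ggplot2::aes(.data$num, .data$state)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$p)) +
    ggplot2::geom_point(data = dplyr::filter(long,
                                             .data$shape == .data$state),
                        size = 0.6, color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "residue", y = "shape state", fill = "posterior") +
    ggplot2::theme_minimal()
}

#' Plot a shape profile
#'
#' Heatmap of the eight-box evidence counts along the chain.
#'
#' @param profile A tibble from [build_profile()].
#' @return A ggplot.
#' @export
plot_profile <- function(profile) {
  long <- profile |>
    tidyr::pivot_longer(dplyr::all_of(shape_states()), names_to = "state",
                        values_to = "count") |>
    dplyr::mutate(state = factor(.data$state, levels = rev(shape_states())))
  ggplot2::ggplot(long, ggplot2::aes(.data$num, .data$state,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "residue", y = "shape state", fill = "hits") +
    ggplot2::theme_minimal()
}
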