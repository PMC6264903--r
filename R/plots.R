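#' Response curves of one output neuron
#'
#' Firing rate as a function of head-centred target location, one curve per
#' test eye position.  A head-centred neuron shows aligned curves; an
#' eye-centred neuron shows curves shifted in register with eye position.
#'
#' @param object a `gf_responses` object.
#' @param neuron output neuron index.
#' @param ... unused.
#' @method autoplot gf_responses
#' @export
autoplot.gf_responses <- function(object, neuron = 1, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(.data$neuron == !!neuron)
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$rate,
                                   colour = factor(.data$eye))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "head-centred target location (deg)",
                  y = "firing rate",
                  colour = "eye position (deg)",
                  title = paste("output neuron", neuron)) +
    ggplot2::theme_minimal()
}

#' Reference-frame scatter plot
#'
#' Each analysed output neuron plotted by its eye-centredness (abscissa) and
#' head-centredness (ordinate); points above the identity line are
#' head-centred, below eye-centred.
#'
#' @param object a classification tibble from [classify_responses()].
#' @param ... unused.
#' @method autoplot gf_classification
#' @export
autoplot.gf_classification <- function(object, ...) {
  df <- dplyr::filter(object, .data$label != "excluded")
  ggplot2::ggplot(df, ggplot2::aes(.data$eye_centredness,
                                   .data$head_centredness,
                                   colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "eye-centredness", y = "head-centredness") +
    ggplot2::theme_minimal()
}

#' Topographic weight-map plot
#'
#' Afferent weights of one output neuron arranged by presynaptic retinal and
#' eye-position preference (facetted by gain direction for sigmoidal or
#' mixed populations).  A learned head-centred neuron shows a diagonal band;
#' an eye-centred neuron a horizontal band.
#'
#' @param model a `gf_model`.
#' @param neuron output neuron index.
#' @export
plot_weight_map <- function(model, neuron = 1) {
  df <- weight_map(model, neuron) |>
    dplyr::filter(!is.na(.data$weight)) |>
    dplyr::mutate(panel = dplyr::case_when(
      .data$kappa_sign > 0 ~ "sigmoid, positive gain",
      .data$kappa_sign < 0 ~ "sigmoid, negative gain",
      TRUE ~ "peaked"))
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$alpha,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "eye-position preference (deg)",
                  y = "retinal preference (deg)", fill = "weight") +
    ggplot2::theme_minimal()
}
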