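# ggplot2 views of the model's objects.

#' Plot a confusion matrix as a tile map
#'
#' One row per stimulus (labelled `A<aud>V<vis>`), one column per response,
#' fill = response proportion.
#'
#' @param object A `cims_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cims_confusion
#' @export
autoplot.cims_confusion <- function(object, ...) {
  tbl <- dplyr::mutate(
    as_tibble(object),
    stimulus = paste0("A", .data$stimulus_auditory,
                      "V", .data$stimulus_visual))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$response,
                                    y = .data$stimulus,
                                    fill = .data$proportion)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$proportion), "",
                     sprintf("%.2f", .data$proportion))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = "response", y = "stimulus", fill = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot the representational space and its decision regions
#'
#' Prototypes in the auditory (x) / visual (y) feature plane, over the
#' categorization regions induced by the shared category covariance plus the
#' fused sensory covariance. With equal category covariances the boundaries
#' are linear.
#'
#' @param config A [model_config()] (noise is needed for the fused
#'   covariance entering the decision rule).
#' @param resolution Grid resolution per axis for the region raster.
#' @param pad Margin added around the prototype bounding box (space units).
#' @return A ggplot object.
#' @export
plot_space <- function(config, resolution = 151L, pad = 0.25) {
  space <- config$space
  covs <- noise_covariances(config$noise)
  sigma_av <- fuse(c(0, 0), c(0, 0), covs$sigma_a_cov,
                   covs$sigma_v_cov)$sigma_av
  protos <- space$prototypes
  xr <- range(protos$x) + c(-pad, pad)
  yr <- range(protos$y) + c(-pad, pad)
  grid <- tidyr::expand_grid(x = seq(xr[1], xr[2], length.out = resolution),
                             y = seq(yr[1], yr[2], length.out = resolution))
  grid$region <- categorize(as.matrix(grid[, c("x", "y")]), sigma_av, space)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region), alpha = 0.35) +
    ggplot2::geom_point(data = protos, size = 2) +
    ggplot2::geom_text(data = protos,
                       ggplot2::aes(label = .data$label),
                       vjust = -0.8, fontface = "bold") +
    ggplot2::labs(x = "auditory feature axis (space units)",
                  y = "visual feature axis (space units)",
                  fill = "percept") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot trial-level representations for one stimulus
#'
#' Scatter of the encoded auditory, visual, fused and final representations
#' across simulated trials, over the decision regions.
#'
#' @inheritParams simulate_stimulus
#' @param n_trials Trials to draw (a few hundred is plenty for a figure).
#' @return A ggplot object.
#' @export
plot_trials <- function(config, auditory, visual,
                        mode = c("cims", "non_cims"), n_trials = 300L,
                        seed = config$seed) {
  mode <- match.arg(mode)
  det <- simulate_stimulus(config, auditory, visual, mode = mode,
                           n_trials = n_trials, seed = seed, details = TRUE)
  long <- dplyr::bind_rows(
    tibble(kind = "auditory (X_A)", x = det$x_a_x, y = det$x_a_y),
    tibble(kind = "visual (X_V)", x = det$x_v_x, y = det$x_v_y),
    tibble(kind = "fused (X_AV)", x = det$x_av_x, y = det$x_av_y),
    tibble(kind = "final", x = det$x_final_x, y = det$x_final_y))
  plot_space(config) +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kind),
                        alpha = 0.35, size = 0.8, inherit.aes = FALSE) +
    ggplot2::labs(title = paste0("A", auditory, "V", visual, " (", mode, ")"),
                  colour = "representation")
}
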