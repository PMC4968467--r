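#' Plot cell means of tracking error against set size
#'
#' Participant-averaged mean tracking error per condition, against the
#' number of squares, split by coloration (colour) and contrast level (solid
#' = maximal contrast, dashed = lower), with within-subject 95% confidence
#' intervals ([within_subject_ci()]).
#'
#' @param trials trial table (practice trials are dropped) or a cell table
#'   from [aggregate_cells()].
#' @param level confidence level for the error bars.
#' @return A ggplot object.
#' @export
plot_cell_means <- function(trials, level = 0.95) {
  cells <- if ("log_error" %in% names(trials)) trials else
    aggregate_cells(trials)
  ci <- within_subject_ci(cells, value_col = "mean_error_px", level = level)
  ggplot2::ggplot(ci, ggplot2::aes(
    x = .data$set_size, y = .data$mean,
    colour = .data$coloration, linetype = .data$contrast,
    shape = .data$contrast,
    group = interaction(.data$coloration, .data$contrast))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci_half,
                                        ymax = .data$mean + .data$ci_half),
                           width = 1.5) +
    ggplot2::scale_linetype_manual(values = c(high = "solid",
                                              low = "dashed")) +
    ggplot2::scale_shape_manual(values = c(high = 16, low = 17)) +
    ggplot2::labs(x = "Number of squares",
                  y = "Mean tracking error (px)",
                  colour = "Coloration", linetype = "Contrast",
                  shape = "Contrast") +
    ggplot2::theme_classic()
}

#' Plot fitted model predictions against set size
#'
#' Population-level predictions of a fitted model on the log-error scale,
#' back-transformed to pixels, over a fine grid of set sizes for each
#' coloration x contrast condition.
#'
#' @param fit an [fit_lmm()] result containing `set_size`, `coloration` and
#'   `contrast` (e.g. a model from [model_ladder()]'s `fits` attribute).
#' @return A ggplot object.
#' @export
plot_fitted_model <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  grid <- expand.grid(set_size = seq(1, 60, by = 1),
                      coloration = fit$xlevels$coloration,
                      contrast = fit$xlevels$contrast,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fitted_px <- exp(predict(fit, grid))
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$set_size, y = .data$fitted_px,
    colour = .data$coloration, linetype = .data$contrast)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(high = "solid",
                                              low = "dashed")) +
    ggplot2::labs(x = "Number of squares",
                  y = "Fitted mean tracking error (px)",
                  colour = "Coloration", linetype = "Contrast") +
    ggplot2::theme_classic()
}
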