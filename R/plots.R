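#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the pose-error distributions of an evaluation report
#'
#' One panel per error metric, grouped by trajectory stage and coloured by
#' method — the standard view of how the error distribution contracts from
#' the initial poses through the coarse and fine stages.
#'
#' @param object A `carm_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carm_eval <- function(object, ...) {
  long <- tidy(object)
  long$stage <- factor(long$stage, levels = c("initial", "stage1", "stage2"),
                       labels = c("initial", "stage 1", "stage 2"))
  long$metric <- factor(long$metric, levels = metric_names(),
                        labels = c("d*theta~(deg)", "d*alpha~(deg)",
                                   "d*beta~(deg)", "d*gamma~(deg)", "dc~(mm)"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$stage, y = .data$value,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", nrow = 1,
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = NULL, y = "error", fill = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the training history of a regressor
#'
#' @param object A trained `carm_regressor`.
#' @param ... Unused.
#' @return A ggplot object of train and validation loss per epoch.
#' @export
autoplot.carm_regressor <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history", call. = FALSE)
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = paste(object$stage, "loss"), colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Display a projection or network input image
#'
#' Grey-level raster with x to the right and y down, as on the detector.
#'
#' @param img A numeric matrix (projection or preprocessed input).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_projection <- function(img, title = NULL) {
  df <- expand.grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$value <- as.vector(unclass_matrix(as.matrix(img)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
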