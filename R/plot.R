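# ggplot2 views of the result objects; all return plain ggplot objects the
# caller can restyle.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attribution track
#'
#' @param object An `attribution_track`.
#' @param ... Unused.
#' @return A ggplot: per-base contribution score along the sequence.
#' @export
autoplot.attribution_track <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "position (bp)", y = "contribution score") +
    ggplot2::theme_minimal()
}

#' Plot a tiling-deletion profile
#'
#' @param object A `deletion_profile`.
#' @param ... Unused.
#' @return A ggplot: prediction drop per deletion-window start.
#' @export
autoplot.deletion_profile <- function(object, ...) {
  ggplot2::ggplot(object$deltas, ggplot2::aes(x = .data$start, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("window start (bp, %d bp windows)", object$window),
                  y = "p(WT) - p(deleted)") +
    ggplot2::theme_minimal()
}

#' Plot a saturation-mutagenesis map
#'
#' @param object A `mutagenesis_map`.
#' @param ... Unused.
#' @return A ggplot heatmap of prediction changes per position and base.
#' @export
autoplot.mutagenesis_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$base,
                               fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "delta p") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object A trained `densenet_model`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch.
#' @export
autoplot.densenet_model <- function(object, ...) {
  h <- tidy(object) %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GIA result
#'
#' @param object A `gia_result`.
#' @param ... Unused.
#' @return A ggplot: distribution of per-background local importances with
#'   the global importance marked.
#' @export
autoplot.gia_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$local_importance)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$global_importance,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("local importance of %s", object$motif),
                  y = "backgrounds") +
    ggplot2::theme_minimal()
}
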