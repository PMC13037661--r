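#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_tile
#'   geom_raster scale_fill_viridis_c scale_fill_gradient2 labs facet_wrap
#'   theme_minimal geom_text
NULL

#' @export
ggplot2::autoplot

#' Plot an accuracy-versus-time decoding series
#'
#' @param object a `decoding_series` ([pointwise_decode()],
#'   [windowwise_decode()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decoding_series <- function(object, ...) {
  ggplot(object$series, aes(x = .data$time, y = .data$accuracy)) +
    geom_line() +
    geom_hline(yintercept = object$chance, linetype = "dashed",
               colour = "grey50") +
    labs(x = "time relative to movement onset (s)", y = "accuracy",
         title = sprintf("%s decoding", object$kind)) +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("true", "predicted", "count")
  ggplot(cm, aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), colour = "white") +
    scale_fill_viridis_c() +
    labs(title = sprintf("accuracy %.1f%%", 100 * object$mean_accuracy)) +
    theme_minimal()
}

#' Plot an activation map
#'
#' Full-epoch maps show task-by-vertex tiles; windowed maps are faceted by
#' task with windows on the x axis.
#'
#' @param object an `activation_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.activation_map <- function(object, ...) {
  df <- tidy(object)
  if (is.null(object$window_length)) {
    ggplot(df, aes(x = .data$vertex, y = .data$task, fill = .data$A)) +
      geom_tile() +
      scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
      labs(x = "vertex", y = "task", fill = "A") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$window, y = .data$vertex, fill = .data$A)) +
      geom_raster() +
      scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
      facet_wrap(~task) +
      labs(x = "50-ms window", y = "vertex", fill = "A") +
      theme_minimal()
  }
}

#' Plot a time-frequency response
#'
#' @param object a `tfr`.
#' @param ... unused.
#' @return a ggplot showing trial-averaged power.
#' @export
autoplot.tfr <- function(object, ...) {
  P <- tfr_average(object)
  df <- tibble::tibble(
    time = rep(object$times, each = length(object$freqs)),
    freq = rep(object$freqs, times = length(object$times)),
    power = as.vector(P)
  )
  ggplot(df, aes(x = .data$time, y = .data$freq, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency (Hz)", fill = "power",
         title = sprintf("%s power", object$kind)) +
    theme_minimal()
}

#' Plot a group digit map
#'
#' @param object a `digit_map`.
#' @param ... unused.
#' @return a ggplot of per-window vertex labels.
#' @export
autoplot.digit_map <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$label), ]
  ggplot(df, aes(x = .data$window, y = .data$vertex, fill = .data$label)) +
    geom_tile() +
    labs(x = "50-ms window", y = "vertex", fill = "finger") +
    theme_minimal()
}
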