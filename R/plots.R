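#' Plot a trial trace
#'
#' @param object A [trial_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nvc_trace <- function(object, ...) {
  m <- trace_meta(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::annotate("rect", xmin = m$stim_onset,
                      xmax = m$stim_onset + m$stim_duration,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = switch(m$modality, calcium = "Ca signal",
                             diameter = "diameter", velocity = "velocity"),
                  title = sprintf("%s trace", m$modality)) +
    ggplot2::theme_minimal()
  if ("sem" %in% names(object))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - object$sem,
                   ymax = .data$value + object$sem), alpha = 0.3)
  p
}

#' Plot a sigmoid fit with its onset markers
#'
#' @param object A `nvc_sigmoid` from [fit_sigmoid()].
#' @param onsets Optional [onset_times()] row to mark (absolute times:
#'   pass `stim_onset = 0` when computing them, or shift beforehand).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nvc_sigmoid <- function(object, onsets = NULL, ...) {
  grid <- seq(min(object$data$time_s), max(object$data$time_s),
              length.out = 400)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_line(data = predict(object, grid), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "z-score",
                  title = "averaged z-score and sigmoid fit") +
    ggplot2::theme_minimal()
  if (!is.null(onsets) && isTRUE(onsets$ok)) {
    marks <- tibble::tibble(
      level = c("t10", "t25", "t50"),
      t = c(onsets$t10, onsets$t25, onsets$t50))
    p <- p + ggplot2::geom_vline(data = marks,
      ggplot2::aes(xintercept = .data$t, colour = .data$level),
      linetype = "dashed")
  }
  p
}

#' Plot a transfer-function kernel
#'
#' @param object A [transfer_function()].
#' @param t_max Plot horizon in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nvc_tf <- function(object, t_max = 20, ...) {
  t <- seq(0, t_max, length.out = 600)
  ggplot2::ggplot(tibble::tibble(time_s = t, value = tf_eval(object, t)),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = tf_mode(object), linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "kernel",
                  title = "gamma-variate transfer function") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph image
#'
#' @param object A [kymograph()].
#' @param ... Unused.
#' @return A ggplot raster of the image (time down, position across).
#' @export
autoplot.nvc_kymograph <- function(object, ...) {
  df <- expand.grid(line = seq_len(nrow(object$image)),
                    px = seq_len(ncol(object$image)))
  df$intensity <- as.vector(object$image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px * object$dx,
                                   y = .data$line * object$dt_line,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "position (um)", y = "time (s)",
                  title = sprintf("kymograph (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Paired state-contrast plot
#'
#' Dot-and-line plot of the paired per-network Pearson correlations (or
#' slopes) achieved by two kernels, as produced by
#' [reproduce_state_contrast()].
#'
#' @param table Tibble with columns `network`, and two paired metrics.
#' @param metrics Names of the two paired columns.
#' @return A ggplot.
#' @export
plot_state_contrast <- function(table, metrics = c("r_aw", "r_an")) {
  long <- tidyr::pivot_longer(table[, c("network", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "kernel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kernel, y = .data$value,
                                     group = .data$network)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(y = "prediction quality", x = NULL,
                  title = "paired kernel comparison") +
    ggplot2::theme_minimal()
}
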