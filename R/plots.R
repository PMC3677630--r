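# ggplot2 helpers for the main result objects.

#' Plot a training log
#'
#' Training error per epoch and output stream, averaged over replicate
#' seeds with SEM ribbons when several seeds were trained.
#'
#' @param object A `hippo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hippo_fit <- function(object, ...) {
  df <- object$log |>
    dplyr::group_by(.data$epoch, .data$output) |>
    dplyr::summarise(
      mean = mean(.data$error),
      sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
            else NA_real_,
      .groups = "drop"
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mean,
                                        colour = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training error",
                  title = paste0(object$variant, " training"),
                  colour = "output")
  if (any(!is.na(df$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem, fill = .data$output),
      alpha = 0.2, colour = NA
    ) + ggplot2::labs(fill = "output")
  }
  p
}

#' Plot a crossconnection sweep
#'
#' Per-output average sample-task error against the crossconnection
#' multiplier, with SEM error bars across seeds.
#'
#' @param object A `hippo_sweep` from [sweep_crossconnections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hippo_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$multiplier, .data$mean,
                               colour = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.05
    ) +
    ggplot2::labs(x = paste(object$side, "crossconnection multiplier"),
                  y = "error", colour = "output",
                  title = paste0(object$variant,
                                 " sample-task error vs crossconnection"))
}

#' Plot a test battery
#'
#' Combined recognition error (mean of the object error and the better
#' context output) against corruption level, one curve per variant,
#' faceted by battery.
#'
#' @param object A `hippo_battery` from [run_battery()].
#' @param output Plot a single output's error instead of the combined
#'   score (e.g. `"O"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hippo_battery <- function(object, output = NULL, ...) {
  df <- if (is.null(output)) {
    object$combined_summary
  } else {
    dplyr::filter(object$summary, .data$output == !!output)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$mean,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.01
    ) +
    ggplot2::facet_wrap(~battery) +
    ggplot2::labs(x = "corruption level", colour = "variant",
                  y = if (is.null(output)) "combined error"
                      else paste(output, "error"))
}

#' Plot a CA3 size sweep
#'
#' @param object A `hippo_ca3_sweep` from [sweep_ca3_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hippo_ca3_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$size, .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.02
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "posterior CA3 size", y = "object-output error",
                  title = "partial-object recall vs CA3 size")
}

#' Bar chart of final training error per variant and output
#'
#' @param comparison Result of [training_error_comparison()].
#' @return A ggplot object.
#' @export
plot_training_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(.data$variant, .data$mean,
                               fill = .data$output)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "final training error", fill = "output")
}
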