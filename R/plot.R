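#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Orthographic snapshot of a configuration on the shell
#'
#' Renders cells as discs on an orthographic projection along the chosen
#' view axis; cells on the far hemisphere are dimmed, mimicking the
#' standard rendering of the shell with the far side darker.
#'
#' @param traj a `killi_trajectory` with frames.
#' @param time time of the frame to draw (nearest recorded frame is used;
#'   defaults to the last).
#' @param view_axis `"z"`, `"y"` or `"x"`: projection axis.
#' @param colour_by `"cluster"` to colour by contact-graph cluster, or
#'   `"none"`.
#' @return a ggplot object.
#' @export
plot_shell_snapshot <- function(traj, time = NULL, view_axis = c("z", "y", "x"),
                                colour_by = c("cluster", "none")) {
  stopifnot(inherits(traj, "killi_trajectory"), !is.null(traj$positions))
  view_axis <- match.arg(view_axis)
  colour_by <- match.arg(colour_by)
  k <- if (is.null(time)) {
    length(traj$times)
  } else {
    which.min(abs(traj$times - time))
  }
  pos <- traj$positions[, , k, drop = TRUE]
  ax <- switch(view_axis, z = c(1, 2, 3), y = c(3, 1, 2), x = c(2, 3, 1))
  df <- tibble::tibble(
    h = pos[, ax[1]], v = pos[, ax[2]], depth = pos[, ax[3]],
    near = pos[, ax[3]] >= 0
  )
  if (colour_by == "cluster") {
    df$cluster <- factor(cpp_find_clusters(pos, traj$config$R))
  }
  RE <- traj$config$RE
  circle <- tibble::tibble(
    h = RE * cos(seq(0, 2 * pi, length.out = 181)),
    v = RE * sin(seq(0, 2 * pi, length.out = 181))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_path(data = circle, colour = "grey70") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("t = %g", traj$times[k]),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
  if (colour_by == "cluster") {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$cluster, alpha = .data$near),
      size = 2, show.legend = FALSE
    )
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(alpha = .data$near),
                                 size = 2, show.legend = FALSE)
  }
  p + ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25))
}

#' @export
autoplot.killi_trajectory <- function(object, ...) {
  plot_shell_snapshot(object, ...)
}

#' Plot a cluster-size time series
#'
#' Maximum cluster size against time, on log-log axes (the convention for
#' aggregation kinetics).
#'
#' @param object a `cluster_series` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cluster_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$max_size)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "maximum cluster size") +
    ggplot2::theme_minimal()
}

#' Plot ensemble aggregation curves
#'
#' Mean maximum cluster size with a band of +/- one standard deviation.
#'
#' @param stats output of [ensemble_stats()].
#' @return a ggplot object.
#' @export
plot_ensemble <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$time, y = .data$mean_max_size)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$mean_max_size - .data$sd_max_size, 1e-10),
        ymax = .data$mean_max_size + .data$sd_max_size
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "maximum cluster size") +
    ggplot2::theme_minimal()
}

#' Phase-diagram heat map of a scan result
#'
#' Mean final maximum cluster size over the adhesion (`Wc`) x CIL (`psi`)
#' grid.
#'
#' @param object a `scan_result` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$Wc), y = factor(.data$psi),
    fill = .data$mean_final_max_size
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "max cluster") +
    ggplot2::labs(x = expression(W[c]), y = expression(psi)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
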