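#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_point geom_hline
#'   facet_wrap labs theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Plot a reconstructed kick trajectory
#'
#' Side view (forward y vs height z) of the foot path, coloured by speed,
#' with the peak-speed sample and the backswing apex marked when present.
#'
#' @param object A `kick_track` (or `kick_truth`) tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kick_track
#' @export
autoplot.kick_track <- function(object, ...) {
  df <- as_tibble(object)
  df$speed <- sqrt(df$vx^2 + df$vy^2 + df$vz^2)
  p <- ggplot(df, aes(x = .data$py, y = .data$pz, colour = .data$speed)) +
    geom_path(linewidth = 0.7) +
    coord_fixed() +
    labs(x = "forward y (m)", y = "height z (m)", colour = "speed (m/s)",
         title = "Foot trajectory (side view)") +
    theme_minimal()
  km <- tryCatch(kick_metrics(df), error = function(e) NULL)
  if (!is.null(km)) {
    marks <- tibble(
      py = c(df$py[km$max_speed_index],
             if (!is.na(km$backswing_apex_index)) df$py[km$backswing_apex_index]),
      pz = c(df$pz[km$max_speed_index],
             if (!is.na(km$backswing_apex_index)) df$pz[km$backswing_apex_index]),
      what = c("peak speed", if (!is.na(km$backswing_apex_index)) "backswing apex")
    )
    p <- p + geom_point(data = marks, aes(x = .data$py, y = .data$pz, shape = .data$what),
                        colour = "black", size = 3)
  }
  p
}

#' @method autoplot kick_truth
#' @export
autoplot.kick_truth <- autoplot.kick_track

#' Bland-Altman plot of an agreement analysis
#'
#' Per-axis scatter of paired differences against paired means, with the bias
#' and the 95% limits of agreement as horizontal lines.
#'
#' @param object A [bland_altman()] or [compare_to_reference()] result.
#' @param ... Unused.
#' @return A ggplot faceted by axis.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pr <- object$pairs
  long <- dplyr::bind_rows(lapply(c("x", "y", "z"), function(ax) {
    mid <- (pr[[paste0("imu_", ax)]] + pr[[paste0("ref_", ax)]]) / 2
    d <- pr[[paste0("imu_", ax)]] - pr[[paste0("ref_", ax)]]
    tibble(axis = ax, mean = mid, diff = d)
  }))
  lines <- tidyr::pivot_longer(object$stats[, c("axis", "bias", "lower", "upper")],
                               cols = c("bias", "lower", "upper"),
                               names_to = "which", values_to = "y")
  ggplot(long, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(data = lines, aes(yintercept = .data$y, linetype = .data$which)) +
    facet_wrap(~axis, scales = "free_x") +
    labs(x = "mean of methods (m)", y = "difference IMU - reference (m)",
         title = "Bland-Altman agreement, per axis") +
    theme_minimal()
}

#' @method autoplot kick_agreement
#' @export
autoplot.kick_agreement <- function(object, ...) autoplot(object$bland_altman, ...)
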