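#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an accelerometer calibration model
#'
#' @param x An `accel_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per axis: `axis, scale, bias`.
#' @method tidy accel_calibration
#' @export
tidy.accel_calibration <- function(x, ...) {
  tibble(axis = c("x", "y", "z"), scale = x$L, bias = x$b)
}

#' @rdname tidy.accel_calibration
#' @return `glance()` returns a one-row tibble: `n, rms_residual`.
#' @method glance accel_calibration
#' @export
glance.accel_calibration <- function(x, ...) {
  tibble(n = x$n, rms_residual = x$rms_residual)
}

#' Tidy kick metrics
#'
#' @param x A [kick_metrics()] object.
#' @param ... Unused.
#' @return `tidy()`: long tibble `metric, value, unit`; `glance()`: one-row
#'   tibble with every metric.
#' @method tidy kick_metrics
#' @export
tidy.kick_metrics <- function(x, ...) {
  tibble(metric = c("path_length", "max_speed", "backswing_height"),
         value = c(x$path_length, x$max_speed, x$backswing_height),
         unit = c("m", "m/s", "m"))
}

#' @rdname tidy.kick_metrics
#' @method glance kick_metrics
#' @export
glance.kick_metrics <- function(x, ...) {
  tibble(path_length = x$path_length,
         max_speed = x$max_speed,
         max_speed_index = x$max_speed_index,
         backswing_height = x$backswing_height,
         backswing_apex_index = x$backswing_apex_index)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return `tidy()`: the per-axis stats tibble; `glance()`: one-row pooled
#'   summary.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$stats

#' @rdname tidy.bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n_total, n_outside = x$n_outside, frac_outside = x$frac_outside)
}

#' Tidy an agreement report
#'
#' @param x A [compare_to_reference()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-axis Bland-Altman tibble; `glance()`: one-row
#'   tibble with the RMSE summaries.
#' @method tidy kick_agreement
#' @export
tidy.kick_agreement <- function(x, ...) x$bland_altman$stats

#' @rdname tidy.kick_agreement
#' @method glance kick_agreement
#' @export
glance.kick_agreement <- function(x, ...) {
  tibble(position_rmse = x$position_rmse,
         velocity_rmse = x$velocity_rmse,
         velocity_rmse_kick_direction = x$velocity_rmse_kick_direction,
         n_pairs = x$n_pairs,
         ba_frac_outside = x$bland_altman$frac_outside)
}
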