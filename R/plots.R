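#' Plot a fish model silhouette
#'
#' Control surfaces as filled polygons with the hinge and COM marked.
#'
#' @param object A [fish_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fish_model
#' @export
autoplot.fish_model <- function(object, ...) {
  polys <- dplyr::bind_rows(lapply(object$surfaces, function(s)
    tibble::tibble(surface = s$name, x = s$vertices[, 1L],
                   y = s$vertices[, 2L])))
  pts <- tibble::tibble(
    what = c("hinge", "COM"),
    x = c(object$hinge_point[1L], object$com_point[1L]),
    y = c(object$hinge_point[2L], object$com_point[2L]))
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$surface,
                                       fill = .data$surface),
                          colour = "grey20", alpha = 0.8) +
    ggplot2::geom_point(data = pts, ggplot2::aes(shape = .data$what),
                        size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$species_id, x = "x (cm)", y = "y (cm)",
                  fill = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the angle series of a flick trial
#'
#' Head--body angle and earthbound body angle against time, with the onset
#' frame marked.
#'
#' @param object A `flick_trial`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flick_trial
#' @export
autoplot.flick_trial <- function(object, ...) {
  ser <- angles_from_landmarks(object)
  meta <- attr(object, "meta")
  long <- tidyr::pivot_longer(ser, c("head_body_deg", "body_earth_deg"),
                              names_to = "angle", values_to = "deg")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$deg,
                                          colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(meta$t0_time_s))
    p <- p + ggplot2::geom_vline(xintercept = meta$t0_time_s,
                                 linetype = "dashed", colour = "grey50")
  p
}

#' Plot the two morphology--kinematics regressions
#'
#' Species-mean head angular speed against head MOI, and species-mean body
#' displacement against relative MOI, with the fitted OLS lines.
#'
#' @param object A `study_models` from [run_study_models()].
#' @param ... Unused.
#' @return A ggplot (two facets).
#' @method autoplot study_models
#' @export
autoplot.study_models <- function(object, ...) {
  panel <- function(fit, label) {
    tibble::tibble(x = fit$data$x, y = fit$data$y, model = label,
                   fitted = fit$intercept + fit$slope * fit$data$x)
  }
  d <- dplyr::bind_rows(
    panel(object$ols_speed, "speed (deg/s) ~ head MOI (g cm^2)"),
    panel(object$ols_displacement,
          "displacement (deg) ~ relative MOI"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::facet_wrap(~model, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
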