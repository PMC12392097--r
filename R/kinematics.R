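#' Head--body and earthbound body angles from landmark trajectories
#'
#' Reproduces the video-analysis step: from the four digitized landmarks,
#' compute per frame (a) the unsigned angle between the head vector
#' (landmark 2 -> 1) and the body vector (landmark 4 -> 3), and (b) the
#' signed, unwrapped earthbound orientation of the body vector in the lab
#' frame.
#'
#' @param trial A `flick_trial` (or any long-format landmark table with
#'   columns `frame`, `time_s`, `landmark`, `x_cm`, `y_cm`).
#' @return An `angle_series` tibble: `frame`, `time_s`, `head_body_deg`
#'   (in `[0, 180)`), `body_earth_deg` (continuous, no 180-degree jumps) and
#'   `ok` (FALSE where a segment's landmarks coincide). Metadata on the
#'   trial is carried through in the `meta` attribute.
#' @export
angles_from_landmarks <- function(trial) {
  stopifnot(all(c("frame", "time_s", "landmark", "x_cm", "y_cm") %in%
                  names(trial)))
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(trial), "frame", "time_s", "landmark",
                  "x_cm", "y_cm"),
    names_from = "landmark", values_from = c("x_cm", "y_cm"))
  need <- c("x_cm_1", "x_cm_2", "x_cm_3", "x_cm_4",
            "y_cm_1", "y_cm_2", "y_cm_3", "y_cm_4")
  if (!all(need %in% names(wide)))
    stop("trial must contain landmarks 1:4 in every frame", call. = FALSE)
  if (nrow(wide) < 2L)
    stop("need at least 2 frames", call. = FALSE)
  hx <- wide$x_cm_1 - wide$x_cm_2; hy <- wide$y_cm_1 - wide$y_cm_2
  bx <- wide$x_cm_3 - wide$x_cm_4; by <- wide$y_cm_3 - wide$y_cm_4
  hn <- sqrt(hx^2 + hy^2); bn <- sqrt(bx^2 + by^2)
  ok <- hn > 0 & bn > 0
  cosang <- pmin(1, pmax(-1, (hx * bx + hy * by) / (hn * bn)))
  head_body <- acos(cosang) * 180 / pi
  head_body[!ok] <- NA_real_
  body_earth_raw <- atan2(by, bx)
  body_earth <- unwrap_angle(body_earth_raw) * 180 / pi
  body_earth[!ok] <- NA_real_
  out <- tibble::tibble(frame = wide$frame, time_s = wide$time_s,
                        head_body_deg = head_body,
                        body_earth_deg = body_earth, ok = ok)
  attr(out, "meta") <- attr(trial, "meta")
  class(out) <- c("angle_series", class(out))
  out
}

# remove +-2*pi jumps so the orientation series is continuous
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

#' Per-trial flick metrics: head angular speed and body displacement
#'
#' Locates the first time the head--body angle reaches `threshold` (45
#' degrees in the study) by linear interpolation between the bracketing
#' frames. Head angular speed is `threshold / (t_end - t0)` (the mean rate
#' over the flick); body displacement is the absolute change of the
#' earthbound body angle between `t0` and `t_end`, both endpoints
#' interpolated.
#'
#' @param series An `angle_series` from [angles_from_landmarks()].
#' @param t0 Motion-onset time, s. Defaults to the trial metadata
#'   (`t0_time_s`) when present, otherwise detected as the first
#'   frame whose head--body angle exceeds `onset_threshold`.
#' @param threshold Stop angle, degrees (> 0; default 45).
#' @param onset_threshold Onset-detection angle, degrees (default 0.1).
#' @param species_id,trial_id Identifiers copied into the output; default to
#'   trial metadata when available.
#' @return A `kinematics_summary`: one-row tibble with `species_id`,
#'   `trial_id`, `head_angular_speed` (deg/s), `body_displacement` (deg),
#'   `t_end` (s, from `t0`), `n_frames`.
#' @export
flick_metrics <- function(series, t0 = NULL, threshold = 45,
                          onset_threshold = 0.1, species_id = NULL,
                          trial_id = NA_character_) {
  stopifnot(inherits(series, "data.frame"),
            all(c("time_s", "head_body_deg", "body_earth_deg") %in%
                  names(series)))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive angle in degrees", call. = FALSE)
  meta <- attr(series, "meta")
  if (is.null(t0) && !is.null(meta$t0_time_s)) t0 <- meta$t0_time_s
  if (is.null(species_id))
    species_id <- if (!is.null(meta$species_id)) meta$species_id
      else NA_character_
  tt <- series$time_s
  ang <- series$head_body_deg
  bod <- series$body_earth_deg
  keep <- !is.na(ang) & !is.na(bod)
  tt <- tt[keep]; ang <- ang[keep]; bod <- bod[keep]
  if (length(tt) < 2L) stop("need at least 2 valid frames", call. = FALSE)
  if (is.null(t0)) {
    idx <- which(ang > onset_threshold)
    if (length(idx) == 0L)
      stop("no motion onset detected (head-body angle never exceeds ",
           onset_threshold, " deg)", call. = FALSE)
    t0 <- tt[idx[1L]]
  }
  if (t0 < tt[1L] || t0 > tt[length(tt)])
    stop("t0 lies outside the series time span", call. = FALSE)
  after <- which(tt >= t0 & ang >= threshold)
  if (length(after) == 0L)
    stop(sprintf("head-body angle never reaches the %g deg threshold",
                 threshold), call. = FALSE)
  k <- after[1L]
  if (k == 1L)
    stop("threshold already exceeded at the first frame", call. = FALSE)
  f <- (threshold - ang[k - 1L]) / (ang[k] - ang[k - 1L])
  t_end_abs <- tt[k - 1L] + f * (tt[k] - tt[k - 1L])
  body_end <- bod[k - 1L] + f * (bod[k] - bod[k - 1L])
  body_t0 <- stats::approx(tt, bod, xout = t0)$y
  t_end <- t_end_abs - t0
  if (t_end <= 0) stop("threshold crossing does not follow t0", call. = FALSE)
  out <- tibble::tibble(
    species_id = species_id,
    trial_id = trial_id,
    head_angular_speed = threshold / t_end,
    body_displacement = abs(body_end - body_t0),
    t_end = t_end,
    n_frames = length(tt)
  )
  class(out) <- c("kinematics_summary", class(out))
  out
}

#' Extract per-trial kinematics straight from a flick trial
#'
#' Convenience wrapper: [angles_from_landmarks()] then [flick_metrics()],
#' using the trial's recorded `t0` when available.
#'
#' @inheritParams flick_metrics
#' @param trial A `flick_trial`.
#' @param ... Passed on to [flick_metrics()].
#' @return A `kinematics_summary` tibble (one row).
#' @export
extract_kinematics <- function(trial, ...) {
  flick_metrics(angles_from_landmarks(trial), ...)
}

#' Aggregate per-trial kinematics to species means
#'
#' Per-species arithmetic means of head angular speed and body displacement
#' across trials (the study averaged 6--10 trials per model), with trial
#' counts and standard deviations.
#'
#' @param summaries A tibble of per-trial rows as produced by
#'   [flick_metrics()] (bind rows across trials first).
#' @return A tibble with one row per species: `species_id`,
#'   `mean_speed_degps`, `mean_displacement_deg`, `n_trials`, `sd_speed`,
#'   `sd_displacement`.
#' @export
aggregate_by_species <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L)
    stop("no trial summaries to aggregate", call. = FALSE)
  stopifnot(all(c("species_id", "head_angular_speed", "body_displacement")
                %in% names(summaries)))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(summaries), .data$species_id),
    mean_speed_degps = mean(.data$head_angular_speed),
    mean_displacement_deg = mean(.data$body_displacement),
    n_trials = dplyr::n(),
    sd_speed = stats::sd(.data$head_angular_speed),
    sd_displacement = stats::sd(.data$body_displacement),
    .groups = "drop"
  )
}
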