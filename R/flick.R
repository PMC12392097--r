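#' Parameters of a spring-driven head flick
#'
#' The physical models store elastic energy in a spring held by a dissolving
#' latch; on release a constant torque rotates the head about its hinge until
#' it reaches `theta_stop` (45 degrees in the study). The same torque acts,
#' with opposite sign, on the body about the model's centre of mass
#' (action--reaction through the spring), so with no resistive torques the
#' angular-momentum balance I_head * w_head = I_lateral * w_body holds exactly
#' at every instant and the body displacement at the stop angle equals
#' relative MOI x theta_stop. Optional quadratic resistive torques
#' (-c * w * |w|) per segment emulate hydrodynamic drag; head drag lengthens
#' the flick, letting the body displacement exceed the momentum-balance
#' prediction as seen on the physical models.
#'
#' @param torque Constant spring torque, g cm^2 / s^2 (> 0).
#' @param head_moi Head MOI about the hinge axis, g cm^2 (> 0).
#' @param lateral_moi Combined body + median-fin MOI about the COM axis,
#'   g cm^2 (> 0).
#' @param drag_coefficient_head,drag_coefficient_body Lumped quadratic drag
#'   coefficients, g cm^2 (>= 0; default 0 = the exact momentum-balance mode).
#' @param theta_stop Head--body angle ending the flick, degrees in (0, 180);
#'   default 45.
#' @param frame_rate Sampling rate of the emitted landmark series, 1/s
#'   (default 250, the study's video rate).
#' @param dt Integrator step, s (default 1e-5; must be < 1/frame_rate).
#' @param max_time Give up if the stop angle is not reached by this time, s.
#' @param seed Optional integer recorded in the metadata (used by
#'   downstream noise).
#' @return A `flick_params` list.
#' @export
flick_params <- function(torque, head_moi, lateral_moi,
                         drag_coefficient_head = 0, drag_coefficient_body = 0,
                         theta_stop = 45, frame_rate = 250, dt = 1e-5,
                         max_time = 5, seed = NULL) {
  if (!is.numeric(torque) || length(torque) != 1L || !is.finite(torque) ||
      torque <= 0)
    stop("torque must be a positive number", call. = FALSE)
  stopifnot(head_moi > 0, lateral_moi > 0,
            drag_coefficient_head >= 0, drag_coefficient_body >= 0,
            theta_stop > 0, theta_stop < 180,
            frame_rate > 0, dt > 0, max_time > 0)
  if (dt >= 1 / frame_rate)
    stop("dt must be smaller than the frame interval 1/frame_rate",
         call. = FALSE)
  structure(list(torque = torque, head_moi = head_moi,
                 lateral_moi = lateral_moi,
                 drag_coefficient_head = drag_coefficient_head,
                 drag_coefficient_body = drag_coefficient_body,
                 theta_stop = theta_stop, frame_rate = frame_rate, dt = dt,
                 max_time = max_time, seed = seed),
            class = "flick_params")
}

# RK4 integration of the two-segment yaw dynamics. States: head angle/rate
# (relative to the body) and body angle/rate (magnitude of the counter-
# rotation), all in radians. Returns the step-level trajectory and the
# interpolated stop-crossing.
integrate_flick <- function(params) {
  tau <- params$torque
  ih <- params$head_moi
  il <- params$lateral_moi
  ch <- params$drag_coefficient_head
  cb <- params$drag_coefficient_body
  dt <- params$dt
  theta_stop <- params$theta_stop * pi / 180

  deriv <- function(s) {
    c(s[2L],
      (tau - ch * s[2L] * abs(s[2L])) / ih,
      s[4L],
      (tau - cb * s[4L] * abs(s[4L])) / il)
  }
  # run past the crossing so the trajectory can be sampled genuinely for the
  # frames after the stop angle (the spring keeps acting; saved sequences run
  # on past the stop angle, which keeps threshold detection robust to noise)
  tail_time <- 12 / params$frame_rate
  n_max <- ceiling((params$max_time + tail_time) / dt) + 2L
  out <- matrix(NA_real_, nrow = n_max, ncol = 5L)
  s <- c(0, 0, 0, 0)
  t <- 0
  out[1L, ] <- c(t, s)
  i <- 1L
  i_cross <- NA_integer_
  while (i < n_max) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    i <- i + 1L
    out[i, ] <- c(t, s)
    if (is.na(i_cross)) {
      if (s[1L] >= theta_stop) i_cross <- i
      else if (t > params$max_time)
        stop(sprintf(
          "head never reached theta_stop = %g deg within max_time = %g s",
          params$theta_stop, params$max_time), call. = FALSE)
    } else if (t >= out[i_cross, 1L] + tail_time) break
  }
  if (is.na(i_cross))
    stop(sprintf(
      "head never reached theta_stop = %g deg within max_time = %g s",
      params$theta_stop, params$max_time), call. = FALSE)
  out <- out[seq_len(i), , drop = FALSE]
  # linear interpolation of the stop crossing within its step
  th0 <- out[i_cross - 1L, 2L]; th1 <- out[i_cross, 2L]
  f <- (theta_stop - th0) / (th1 - th0)
  t_end <- out[i_cross - 1L, 1L] + f * dt
  interp_row <- out[i_cross - 1L, 2:5] +
    f * (out[i_cross, 2:5] - out[i_cross - 1L, 2:5])
  list(steps = out, t_end = t_end,
       theta_body_end = interp_row[3L],
       omega_head_end = interp_row[2L])
}

#' Simulate a latch-released head flick
#'
#' Integrates the yaw dynamics (classical fixed-step 4th-order Runge--Kutta)
#' until the head--body angle reaches `theta_stop`, then emits the four
#' landmark trajectories sampled at `frame_rate`. Sequences start 10 frames
#' before motion onset, mirroring the saved video sequences; `t0_index` marks
#' the release frame. Sign convention: the head flicks to the model's left
#' (positive yaw); the body counter-rotates (negative earthbound angle).
#'
#' @param params A [flick_params()].
#' @param geometry A [fish_model()] supplying hinge, COM and the four
#'   reference landmarks.
#' @param pre_frames Frames of stillness before release (default 10).
#' @return A `flick_trial`: tibble with columns `frame`, `time_s`,
#'   `landmark` (1--4), `x_cm`, `y_cm`, carrying a `meta` attribute with the
#'   parameters, geometry reference, `t0_index`, and the integrator's own
#'   `t_end_s` (time from release to the stop angle), `head_speed_degps`
#'   (theta_stop / t_end) and `body_displacement_deg` at the stop angle.
#' @examples
#' \donttest{
#' m <- reference_model()
#' p <- flick_params(torque = 1e6, head_moi = 2000, lateral_moi = 4e5)
#' tr <- simulate_flick(p, m)
#' attr(tr, "meta")$head_speed_degps
#' }
#' @export
simulate_flick <- function(params, geometry, pre_frames = 10L) {
  stopifnot(inherits(params, "flick_params"), inherits(geometry, "fish_model"),
            pre_frames >= 0)
  sim <- integrate_flick(params)
  fps <- params$frame_rate
  n_post <- floor(sim$t_end * fps) + 11L # ten frames beyond the stop crossing
  t_post <- (seq_len(n_post) - 1L) / fps
  # interpolate step states at frame times
  th_h <- stats::approx(sim$steps[, 1L], sim$steps[, 2L], xout = t_post,
                        rule = 2)$y
  th_b <- stats::approx(sim$steps[, 1L], sim$steps[, 4L], xout = t_post,
                        rule = 2)$y
  n_pre <- as.integer(pre_frames)
  th_h <- c(rep(0, n_pre), th_h)
  th_b <- c(rep(0, n_pre), th_b)
  n_frames <- length(th_h)
  times <- (seq_len(n_frames) - 1L) / fps

  lm <- landmark_frames(geometry, th_h, th_b)
  trial <- tibble::tibble(
    frame = rep(seq_len(n_frames), each = 4L),
    time_s = rep(times, each = 4L),
    landmark = rep(1:4, times = n_frames),
    x_cm = as.vector(t(lm$x)),
    y_cm = as.vector(t(lm$y))
  )
  meta <- list(params = unclass(params),
               species_id = geometry$species_id,
               t0_index = n_pre + 1L,
               t0_time_s = times[n_pre + 1L],
               frame_rate = fps,
               t_end_s = sim$t_end,
               head_speed_degps = params$theta_stop / sim$t_end,
               body_displacement_deg = sim$theta_body_end * 180 / pi,
               relative_moi = params$head_moi / params$lateral_moi,
               sigma_noise_cm = 0)
  attr(trial, "meta") <- meta
  class(trial) <- c("flick_trial", class(trial))
  trial
}

# Rigid-body landmark positions in the ventral (yaw) plane: the body
# (landmarks 3, 4) rotates by -th_b about the COM; the hinge rides on the
# body; the head (landmark 1) rotates by th_h - th_b about the moved hinge.
# Landmark 2 stays at the hinge. Rotation centres are the hinge and COM
# projected onto the midline (a laterally symmetric model yaws about the
# midline axis).
landmark_frames <- function(geometry, th_h, th_b) {
  ref <- geometry$landmarks
  com <- c(geometry$com_point[1L], 0)
  hinge <- c(geometry$hinge_point[1L], 0)
  n <- length(th_h)
  rot <- function(ang, px, py, cx, cy) {
    ca <- cos(ang); sa <- sin(ang)
    list(x = cx + ca * (px - cx) - sa * (py - cy),
         y = cy + sa * (px - cx) + ca * (py - cy))
  }
  phi_b <- -th_b              # body earthbound angle
  phi_h <- phi_b + th_h       # head earthbound rotation
  hng <- rot(phi_b, hinge[1L], hinge[2L], com[1L], com[2L])
  x <- matrix(NA_real_, n, 4L); y <- matrix(NA_real_, n, 4L)
  # head landmark 1: position relative to the hinge, rotated by phi_h
  dx1 <- ref[1L, 1L] - hinge[1L]; dy1 <- ref[1L, 2L] - hinge[2L]
  x[, 1L] <- hng$x + cos(phi_h) * dx1 - sin(phi_h) * dy1
  y[, 1L] <- hng$y + sin(phi_h) * dx1 + cos(phi_h) * dy1
  x[, 2L] <- hng$x; y[, 2L] <- hng$y
  for (k in 3:4) {
    p <- rot(phi_b, ref[k, 1L], ref[k, 2L], com[1L], com[2L])
    x[, k] <- p$x; y[, k] <- p$y
  }
  list(x = x, y = y)
}

#' Add digitization noise to a flick trial
#'
#' Emulates manual landmark digitization error: independent isotropic
#' Gaussian displacement of scale `sigma` (cm) on every landmark in every
#' frame. Deterministic under a fixed seed.
#'
#' @param trial A `flick_trial`.
#' @param sigma Per-coordinate noise scale, cm (>= 0). The per-landmark RMS
#'   displacement is `sigma * sqrt(2)`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `flick_trial` with perturbed coordinates; `sigma = 0` returns
#'   the input unchanged.
#' @export
add_measurement_noise <- function(trial, sigma, seed = NULL) {
  stopifnot(inherits(trial, "flick_trial"), is.numeric(sigma),
            length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(trial)
  n <- nrow(trial)
  noisy <- with_seed(seed, {
    trial$x_cm <- trial$x_cm + stats::rnorm(n, 0, sigma)
    trial$y_cm <- trial$y_cm + stats::rnorm(n, 0, sigma)
    trial
  })
  meta <- attr(noisy, "meta")
  meta$sigma_noise_cm <- sigma
  attr(noisy, "meta") <- meta
  noisy
}

# evaluate expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write / read a flick trial as CSV plus JSON sidecar
#'
#' The CSV is the long-format trajectory (`frame`, `time_s`, `landmark`,
#' `x_cm`, `y_cm`); the sidecar carries the simulation parameters, seed and
#' `t0_index` -- the format the kinematics module reads.
#'
#' @param trial A `flick_trial`.
#' @param csv_path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `read_trial()` returns a `flick_trial`; `write_trial()` the CSV
#'   path, invisibly.
#' @export
write_trial <- function(trial, csv_path) {
  stopifnot(inherits(trial, "flick_trial"))
  utils::write.csv(as.data.frame(trial), csv_path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(attr(trial, "meta"), side, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(csv_path)
}

#' @rdname write_trial
#' @export
read_trial <- function(csv_path) {
  tab <- tibble::as_tibble(utils::read.csv(csv_path))
  stopifnot(all(c("frame", "time_s", "landmark", "x_cm", "y_cm") %in%
                  names(tab)))
  side <- sub("\\.csv$", ".json", csv_path)
  if (file.exists(side))
    attr(tab, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  class(tab) <- c("flick_trial", class(tab))
  tab
}
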