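#' Calibration constants of the silhouette generator
#'
#' The generator anchors synthetic morphology to the study conditions: every
#' head is normalised to 30 cm^2 projected area; head MOIs about the hinge
#' span the empirical band 1969--3534 g cm^2 (about 2-fold, shape variation
#' only); body MOIs span roughly 4-fold across 124,000--468,000 g cm^2.
#' Standardized traits reach the log-MOI bands through a saturating (tanh)
#' link, reflecting the bounded range of head elongation at fixed area.
#' @keywords internal
SILHOUETTE_CAL <- list(
  head_area = 30,
  head_taper = 0.55,                    # snout depth / base depth
  head_logmoi_center = log(sqrt(1969 * 3534)),
  head_logmoi_halfwidth = 0.97 * log(3534 / 1969) / 2,
  head_tanh_scale = 1.1,
  body_logmoi_center = log(sqrt(95000 * 350000)),
  body_logmoi_halfwidth = 0.97 * log(350000 / 95000) / 2,
  body_tanh_scale = 1.0,
  body_aspect = 0.35,                   # max depth / body length
  # body height profile g(u), u = x / body length
  body_profile_u = c(0, 0.3, 0.65, 1),
  body_profile_g = c(0.55, 1, 0.75, 0.28),
  fin_tanh_scale = 1.2,
  fin_log_amp = 0.3
)

# Exact moments of a piecewise-linear height profile h(x):
# returns A = integral h, M1 = integral x h, M2 = integral x^2 h.
profile_moments <- function(xs, hs) {
  stopifnot(length(xs) == length(hs), length(xs) >= 2L)
  A <- M1 <- M2 <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1L]
    b <- (hs[i + 1L] - hs[i]) / (x1 - x0)
    a <- hs[i] - b * x0
    A <- A + a * (x1 - x0) + b * (x1^2 - x0^2) / 2
    M1 <- M1 + a * (x1^2 - x0^2) / 2 + b * (x1^3 - x0^3) / 3
    M2 <- M2 + a * (x1^3 - x0^3) / 3 + b * (x1^4 - x0^4) / 4
  }
  c(A = A, M1 = M1, M2 = M2)
}

#' Head polygon with fixed area and controllable mass distribution
#'
#' A trapezoid spanning the hinge (at the origin) to the snout at `-length`:
#' deep at the base, tapering toward the mouth. At fixed area, a larger
#' `taper` (snout depth / base depth) or a longer head shifts mass away from
#' the hinge and raises the head MOI.
#'
#' @param area Projected area, cm^2.
#' @param length Head length, cm.
#' @param taper Snout/base depth ratio in (0, 2].
#' @return A 4 x 2 vertex matrix (cm), hinge edge on x = 0.
#' @export
head_polygon <- function(area = 30, length, taper = 0.55) {
  stopifnot(area > 0, length > 0, taper > 0, taper <= 2)
  d_base <- 2 * area / (length * (1 + taper))
  d_snout <- taper * d_base
  cbind(x = c(0, 0, -length, -length),
        y = c(-d_base / 2, d_base / 2, d_snout / 2, -d_snout / 2))
}

# analytic head MOI (g cm^2) about the hinge axis for head_polygon()
head_moi_analytic <- function(area, length, taper, density = 1.44) {
  d_base <- 2 * area / (length * (1 + taper))
  density * length^3 * d_base * (1 / 12 + taper / 4)
}

# invert: head length giving a target MOI at fixed area and taper
head_length_for_moi <- function(moi, area = 30, taper = 0.55,
                                density = 1.44) {
  k <- density * (2 * area / (1 + taper)) * (1 / 12 + taper / 4)
  sqrt(moi / k)
}

#' Build a parametric fish silhouette from one species' trait row
#'
#' Maps standardized trait deviations to a [fish_model()]: head shape sets
#' the head MOI at fixed 30 cm^2 area (longer, less hinge-concentrated heads
#' have higher MOI); body depth/size sets the body MOI; fin size traits scale
#' the four fins. The hinge sits at the head--body junction (the origin); the
#' COM is computed from surface masses.
#'
#' @param traits A one-row data frame (or named list) with columns
#'   `species_id` and the six [trait_names()] (standardized deviations,
#'   typically from [simulate_traits()]).
#' @param head_area Head area target, cm^2 (default 30).
#' @param head_density,fin_density Areal densities, g/cm^2 (defaults 1.44 and
#'   0.475: PVC sheet for head/body, thinner sheet for fins).
#' @param cal Calibration list; see `SILHOUETTE_CAL`.
#' @return A [fish_model()].
#' @export
build_silhouette <- function(traits, head_area = 30, head_density = 1.44,
                             fin_density = 0.475, cal = SILHOUETTE_CAL) {
  tr <- as.list(traits)
  need <- c("species_id", trait_names())
  if (!all(need %in% names(tr)))
    stop("traits must contain: ", paste(need, collapse = ", "), call. = FALSE)
  vals <- unlist(tr[trait_names()])
  if (!all(is.finite(vals)))
    stop("trait values must be finite", call. = FALSE)
  squash <- function(z, scale) tanh(z / scale)

  # head: invert the target MOI to a length at fixed taper and area
  head_target <- exp(cal$head_logmoi_center + cal$head_logmoi_halfwidth *
                       squash(tr$head_moi_shape, cal$head_tanh_scale))
  head_len <- head_length_for_moi(head_target, area = head_area,
                                  taper = cal$head_taper,
                                  density = head_density)
  head_v <- head_polygon(head_area, head_len, cal$head_taper)

  # body: invert the target centroid MOI to a length at fixed aspect/profile
  body_target <- exp(cal$body_logmoi_center + cal$body_logmoi_halfwidth *
                       squash(tr$body_depth, cal$body_tanh_scale))
  gm <- profile_moments(cal$body_profile_u, cal$body_profile_g)
  Cshape <- gm["M2"] - gm["M1"]^2 / gm["A"]
  body_len <- (body_target / (head_density * cal$body_aspect * Cshape))^(1 / 4)
  body_depth <- cal$body_aspect * body_len
  bu <- cal$body_profile_u * body_len
  bg <- cal$body_profile_g * body_depth
  body_v <- cbind(x = c(bu, rev(bu)), y = c(-bg / 2, rev(bg) / 2))

  fin_scale <- function(z) exp(cal$fin_log_amp * squash(z, cal$fin_tanh_scale))
  top_at <- function(x) stats::approx(bu, bg / 2, xout = x)$y
  tri <- function(x1, x2, xa, h, side) {
    y1 <- side * top_at(x1); y2 <- side * top_at(x2)
    cbind(x = c(x1, x2, xa), y = c(y1, y2, side * (max(abs(y1), abs(y2)) + h)))
  }
  caudal_s <- fin_scale(tr$caudal_size)
  ped <- bg[length(bg)]
  caudal_len <- 0.25 * body_len * caudal_s
  caudal_tip <- 0.65 * body_depth * caudal_s
  caudal_v <- cbind(
    x = c(body_len, body_len + caudal_len, body_len + caudal_len, body_len),
    y = c(-ped / 2, -caudal_tip / 2, caudal_tip / 2, ped / 2))
  dorsal_v <- tri(0.20 * body_len, 0.55 * body_len, 0.35 * body_len,
                  0.50 * body_depth * fin_scale(tr$dorsal_size), +1)
  anal_v <- tri(0.45 * body_len, 0.75 * body_len, 0.60 * body_len,
                0.45 * body_depth * fin_scale(tr$anal_size), -1)
  pelvic_v <- tri(0.08 * body_len, 0.22 * body_len, 0.15 * body_len,
                  0.30 * body_depth * fin_scale(tr$pelvic_size), -1)

  surfaces <- list(
    control_surface("head", head_v, head_density),
    control_surface("body", body_v, head_density),
    control_surface("dorsal_fin", dorsal_v, fin_density),
    control_surface("anal_fin", anal_v, fin_density),
    control_surface("caudal_fin", caudal_v, fin_density),
    control_surface("pelvic_fin", pelvic_v, fin_density)
  )
  fish_model(as.character(tr$species_id), surfaces, hinge_point = c(0, 0),
             head_area_target = head_area)
}

#' A single reference fish model for examples and quick tests
#'
#' The silhouette built from all-zero trait deviations (band-centre head and
#' body MOIs, unit fin scales).
#'
#' @param species_id Identifier (default `"reference"`).
#' @return A [fish_model()].
#' @export
reference_model <- function(species_id = "reference") {
  tr <- c(list(species_id = species_id),
          stats::setNames(as.list(rep(0, 6)), trait_names()))
  build_silhouette(tr)
}

#' Generate a complete synthetic study
#'
#' The full bundle the analysis consumes, with the statistical structure the
#' study assumes: a pure-birth ultrametric phylogeny, correlated traits
#' evolved along it under an OU process, parametric silhouettes normalised to
#' 30 cm^2 head area, per-model MOI summaries, and 6--10 simulated flick
#' trials per species with torque jitter and landmark digitization noise.
#' Everything is reproducible under `seed`.
#'
#' @param config A [trait_config()] (default: 17 species, the study's sample
#'   size).
#' @param seed Integer seed.
#' @param trials_range Integer range of trials per species (default
#'   `c(6, 10)`).
#' @param torque_mean Mean spring torque, g cm^2/s^2. The default, with the
#'   default drag scales, places species mean head speeds inside the
#'   empirical 600--1150 deg/s band.
#' @param torque_cv Trial-to-trial lognormal torque jitter (default 0.02).
#' @param drag_scale_head,drag_scale_body Quadratic drag coefficients as
#'   multiples of the respective MOIs (dimensionless; defaults 3.2). Set both
#'   to 0 for the exact momentum-balance (drag-free) study.
#' @param sigma_noise Landmark digitization noise, cm (default 0.02).
#' @param theta_stop,frame_rate,dt Passed to [flick_params()].
#' @param keep_trials Keep the landmark-level trials in the result (default
#'   TRUE; set FALSE to save memory once kinematics are extracted).
#' @return A `study_dataset`: list with `tree`, `traits`, `models`, `moi`
#'   (list of `moi_result`), `species` (per-species tibble joining MOIs and
#'   mean kinematics), `trial_kinematics` (per-trial tibble), `trials`
#'   (list of `flick_trial` or NULL), and `config` (the generation settings).
#' @export
generate_study <- function(config = trait_config(), seed = 1,
                           trials_range = c(6L, 10L),
                           torque_mean = 3.2e6, torque_cv = 0.02,
                           drag_scale_head = 3.2, drag_scale_body = 3.2,
                           sigma_noise = 0.02, theta_stop = 45,
                           frame_rate = 250, dt = 1e-5, keep_trials = TRUE) {
  stopifnot(inherits(config, "trait_config"),
            length(trials_range) == 2L, trials_range[1L] >= 1L,
            trials_range[2L] >= trials_range[1L],
            torque_mean > 0, torque_cv >= 0, sigma_noise >= 0,
            drag_scale_head >= 0, drag_scale_body >= 0)
  gen <- function() {
    tree <- generate_phylogeny(config$n_species, seed = NULL)
    traits <- simulate_traits(tree, config)
    models <- lapply(seq_len(nrow(traits)), function(i)
      build_silhouette(traits[i, ]))
    names(models) <- traits$species_id
    moi <- lapply(models, summarize_model)
    trials <- list()
    kin_rows <- list()
    for (i in seq_along(models)) {
      sp <- names(models)[i]
      n_tr <- sample(seq(trials_range[1L], trials_range[2L]), 1L)
      for (k in seq_len(n_tr)) {
        tau <- torque_mean * exp(stats::rnorm(1, 0, torque_cv))
        params <- flick_params(
          torque = tau,
          head_moi = moi[[i]]$head_moi,
          lateral_moi = moi[[i]]$lateral_moi,
          drag_coefficient_head = drag_scale_head * moi[[i]]$head_moi,
          drag_coefficient_body = drag_scale_body * moi[[i]]$lateral_moi,
          theta_stop = theta_stop, frame_rate = frame_rate, dt = dt)
        trial <- simulate_flick(params, models[[i]])
        if (sigma_noise > 0)
          trial <- add_measurement_noise(trial, sigma_noise, seed = NULL)
        trial_id <- sprintf("%s_t%02d", sp, k)
        kin_rows[[trial_id]] <- extract_kinematics(trial, trial_id = trial_id)
        if (keep_trials) trials[[trial_id]] <- trial
      }
    }
    list(tree = tree, traits = traits, models = models, moi = moi,
         trial_kinematics = dplyr::bind_rows(kin_rows),
         trials = if (keep_trials) trials else NULL)
  }
  parts <- with_seed(seed, gen())
  species_kin <- aggregate_by_species(parts$trial_kinematics)
  moi_tab <- tibble::tibble(
    species_id = names(parts$moi),
    head_moi = vapply(parts$moi, `[[`, numeric(1), "head_moi"),
    lateral_moi = vapply(parts$moi, `[[`, numeric(1), "lateral_moi"),
    pelvic_moi = vapply(parts$moi, `[[`, numeric(1), "pelvic_moi"),
    relative_moi = vapply(parts$moi, `[[`, numeric(1), "relative_moi"))
  species <- dplyr::left_join(moi_tab, species_kin, by = "species_id")
  structure(list(tree = parts$tree, traits = parts$traits,
                 models = parts$models, moi = parts$moi, species = species,
                 trial_kinematics = parts$trial_kinematics,
                 trials = parts$trials,
                 config = list(trait_config = config, seed = seed,
                               trials_range = trials_range,
                               torque_mean = torque_mean,
                               torque_cv = torque_cv,
                               drag_scale_head = drag_scale_head,
                               drag_scale_body = drag_scale_body,
                               sigma_noise = sigma_noise,
                               theta_stop = theta_stop,
                               frame_rate = frame_rate, dt = dt)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d species, %d trials\n",
              nrow(x$species), nrow(x$trial_kinematics)))
  cat(sprintf("  head MOI %.0f-%.0f g cm^2; lateral MOI %.0f-%.0f g cm^2\n",
              min(x$species$head_moi), max(x$species$head_moi),
              min(x$species$lateral_moi), max(x$species$lateral_moi)))
  if (!all(is.na(x$species$mean_speed_degps)))
    cat(sprintf("  mean speeds %.0f-%.0f deg/s; displacements %.2f-%.2f deg\n",
                min(x$species$mean_speed_degps),
                max(x$species$mean_speed_degps),
                min(x$species$mean_displacement_deg),
                max(x$species$mean_displacement_deg)))
  invisible(x)
}

#' Per-species table of a study dataset
#'
#' @param study A `study_dataset`.
#' @return Tibble with one row per species: MOI summaries joined to mean
#'   kinematics.
#' @export
species_table <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  study$species
}

#' Write a study dataset to a directory
#'
#' Writes the Newick tree, trait CSV, per-species silhouette JSONs, per-trial
#' CSV/JSON bundles, MOI and kinematics CSVs, and a manifest JSON recording
#' the seed and configuration.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(study$tree, file.path(dir, "phylogeny.nwk"))
  utils::write.csv(study$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  sil_dir <- file.path(dir, "silhouettes")
  dir.create(sil_dir, showWarnings = FALSE)
  for (m in study$models)
    write_silhouette_json(m, file.path(sil_dir,
                                       paste0(m$species_id, ".json")))
  write_moi_csv(study$moi, file.path(dir, "moi.csv"))
  utils::write.csv(study$trial_kinematics,
                   file.path(dir, "trial_kinematics.csv"), row.names = FALSE)
  utils::write.csv(study$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  if (!is.null(study$trials)) {
    tr_dir <- file.path(dir, "trials")
    dir.create(tr_dir, showWarnings = FALSE)
    for (id in names(study$trials))
      write_trial(study$trials[[id]], file.path(tr_dir, paste0(id, ".csv")))
  }
  jsonlite::write_json(study$config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
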