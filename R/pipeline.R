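#' Study configuration
#'
#' Bundles every tunable of the end-to-end pipeline with the study's default
#' constants: 17 species, 6--10 trials each, areal densities 1.44 g/cm^2
#' (head/body) and 0.475 g/cm^2 (fins), 30 cm^2 head area, strip widths
#' 0.5 cm (head, fins) and 0.7 cm (body), 45-degree stop angle, 250 fps.
#'
#' @param seed Integer master seed.
#' @param n_species Number of species (default 17).
#' @param trials_range Trials per species, length-2 integer range (default
#'   `c(6, 10)`).
#' @param head_strip_width,body_strip_width,fin_strip_width Strip widths, cm.
#' @param head_density,fin_density Areal densities, g/cm^2.
#' @param head_area Head area target, cm^2.
#' @param torque_mean,torque_cv Spring torque distribution (g cm^2/s^2,
#'   lognormal CV across trials).
#' @param drag_scale_head,drag_scale_body Drag coefficients as multiples of
#'   the MOIs.
#' @param sigma_noise Landmark noise, cm.
#' @param theta_stop,frame_rate,dt Flick simulation settings.
#' @param ou_alpha OU strength of trait evolution per unit tree height.
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, n_species = 17,
                         trials_range = c(6L, 10L),
                         head_strip_width = 0.5, body_strip_width = 0.7,
                         fin_strip_width = 0.5, head_density = 1.44,
                         fin_density = 0.475, head_area = 30,
                         torque_mean = 3.2e6, torque_cv = 0.02,
                         drag_scale_head = 3.2, drag_scale_body = 3.2,
                         sigma_noise = 0.02, theta_stop = 45,
                         frame_rate = 250, dt = 1e-5, ou_alpha = 1) {
  cfg <- list(seed = seed, n_species = n_species,
              trials_range = as.integer(trials_range),
              head_strip_width = head_strip_width,
              body_strip_width = body_strip_width,
              fin_strip_width = fin_strip_width,
              head_density = head_density, fin_density = fin_density,
              head_area = head_area, torque_mean = torque_mean,
              torque_cv = torque_cv, drag_scale_head = drag_scale_head,
              drag_scale_body = drag_scale_body, sigma_noise = sigma_noise,
              theta_stop = theta_stop, frame_rate = frame_rate, dt = dt,
              ou_alpha = ou_alpha)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  req <- names(formals(study_config))
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0L)
    stop("study config lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  with(cfg, {
    stopifnot(n_species >= 3, length(trials_range) == 2L,
              trials_range[1L] >= 1L, trials_range[2L] >= trials_range[1L],
              head_strip_width > 0, body_strip_width > 0,
              fin_strip_width > 0, head_density > 0, fin_density > 0,
              head_area > 0, torque_mean > 0, torque_cv >= 0,
              drag_scale_head >= 0, drag_scale_body >= 0, sigma_noise >= 0,
              theta_stop > 0, theta_stop < 180, frame_rate > 0, dt > 0,
              dt < 1 / frame_rate, all(ou_alpha >= 0))
  })
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [study_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(study_config, raw)
}

#' Run the end-to-end analysis pipeline
#'
#' generate -> MOI -> simulate -> extract -> fit, writing every intermediate
#' artifact (tree, traits, silhouettes, MOI table, trials, kinematics,
#' statistical report) plus a manifest into `out_dir`. Reruns with the same
#' configuration are identical.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory.
#' @param keep_trials Write per-trial landmark CSVs (default TRUE; the
#'   heaviest artifact).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the `study_dataset`, the fitted
#'   `study_models` and `out_dir`.
#' @export
run_pipeline <- function(config = study_config(), out_dir,
                         keep_trials = TRUE, quiet = FALSE) {
  validate_study_config(config)
  say <- function(...) if (!quiet) message("[flickmorph] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  say("generate: %d species, trials %d-%d, seed %d", config$n_species,
      config$trials_range[1L], config$trials_range[2L], config$seed)
  study <- stage("generate", generate_study(
    config = trait_config(n_species = config$n_species,
                          ou_alpha = config$ou_alpha),
    seed = config$seed, trials_range = config$trials_range,
    torque_mean = config$torque_mean, torque_cv = config$torque_cv,
    drag_scale_head = config$drag_scale_head,
    drag_scale_body = config$drag_scale_body,
    sigma_noise = config$sigma_noise, theta_stop = config$theta_stop,
    frame_rate = config$frame_rate, dt = config$dt,
    keep_trials = keep_trials))
  say("moi: head MOI %.0f-%.0f g cm^2, lateral %.0f-%.0f g cm^2",
      min(study$species$head_moi), max(study$species$head_moi),
      min(study$species$lateral_moi), max(study$species$lateral_moi))
  say("kinematics: %d trials, mean speeds %.0f-%.0f deg/s",
      nrow(study$trial_kinematics), min(study$species$mean_speed_degps),
      max(study$species$mean_speed_degps))
  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_study(study, out_dir)
  })
  say("stats: fitting regressions and phylogenetic correlations")
  models <- stage("stats", run_study_models(study))
  stage("report", write_report(models, file.path(out_dir, "report")))
  say("done: %s", normalizePath(out_dir))
  invisible(list(study = study, models = models, out_dir = out_dir))
}

#' Reconstruct a study dataset from a study directory
#'
#' Reads the artifacts written by [write_study()] / [run_pipeline()] -- tree,
#' traits, silhouette JSONs and per-trial kinematics -- recomputing the MOI
#' summaries from the silhouettes, so downstream stages can be rerun from
#' disk.
#'
#' @param dir A study directory.
#' @return A `study_dataset` (without the landmark-level trials).
#' @export
read_study <- function(dir) {
  need <- c("phylogeny.nwk", "traits.csv", "silhouettes")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L)
    stop("not a study directory; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tree <- ape::read.tree(file.path(dir, "phylogeny.nwk"))
  traits <- tibble::as_tibble(utils::read.csv(file.path(dir, "traits.csv")))
  sil <- list.files(file.path(dir, "silhouettes"), pattern = "\\.json$",
                    full.names = TRUE)
  models <- lapply(sil, read_silhouette_json)
  names(models) <- vapply(models, `[[`, character(1), "species_id")
  models <- models[traits$species_id]
  moi <- lapply(models, summarize_model)
  kin_path <- file.path(dir, "trial_kinematics.csv")
  trial_kin <- if (file.exists(kin_path))
    tibble::as_tibble(utils::read.csv(kin_path))
  else extract_study_trials(file.path(dir, "trials"))
  species_kin <- aggregate_by_species(trial_kin)
  moi_tab <- tibble::tibble(
    species_id = names(moi),
    head_moi = vapply(moi, `[[`, numeric(1), "head_moi"),
    lateral_moi = vapply(moi, `[[`, numeric(1), "lateral_moi"),
    pelvic_moi = vapply(moi, `[[`, numeric(1), "pelvic_moi"),
    relative_moi = vapply(moi, `[[`, numeric(1), "relative_moi"))
  manifest <- file.path(dir, "manifest.json")
  config <- if (file.exists(manifest))
    jsonlite::read_json(manifest, simplifyVector = TRUE) else list()
  structure(list(tree = tree, traits = traits, models = models, moi = moi,
                 species = dplyr::left_join(moi_tab, species_kin,
                                            by = "species_id"),
                 trial_kinematics = trial_kin, trials = NULL,
                 config = config),
            class = "study_dataset")
}

#' Extract kinematics for every trial CSV in a directory
#'
#' @param trials_dir Directory of trial CSV + JSON sidecar bundles.
#' @return Per-trial kinematics tibble.
#' @export
extract_study_trials <- function(trials_dir) {
  files <- list.files(trials_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no trial CSVs found in ", trials_dir, call. = FALSE)
  dplyr::bind_rows(lapply(files, function(f)
    extract_kinematics(read_trial(f),
                       trial_id = sub("\\.csv$", "", basename(f)))))
}
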