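#' Closed-form simple linear regression
#'
#' Ordinary least squares of one response on one predictor via the normal
#' equations, with slope/intercept standard errors from the residual
#' variance, adjusted R^2, the F(1, n-2) statistic and its two-sided p-value.
#' Used for the morphology--kinematics models, which are deliberately
#' non-phylogenetic: the physical models are powered by the same spring
#' mechanism regardless of species identity, so shared ancestry explains no
#' variation in the driving forces.
#'
#' @param data A data frame.
#' @param x,y Bare column names (tidy evaluation) of predictor and response.
#' @return A `flick_ols` object; see [tidy.flick_ols()] and
#'   [glance.flick_ols()].
#' @examples
#' fit_ols(data.frame(a = 1:5, b = 2 * (1:5) + 1), a, b)
#' @export
fit_ols <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  sxx <- sum((xv - mean(xv))^2)
  if (sxx <= 0) stop("predictor has zero variance", call. = FALSE)
  sxy <- sum((xv - mean(xv)) * (yv - mean(yv)))
  syy <- sum((yv - mean(yv))^2)
  slope <- sxy / sxx
  intercept <- mean(yv) - slope * mean(xv)
  resid <- yv - intercept - slope * xv
  rss <- sum(resid^2)
  df_den <- n - 2L
  degenerate <- syy <= .Machine$double.eps * max(1, mean(yv)^2) * n
  if (degenerate) {
    # constant response: slope 0, no explainable variance
    slope <- 0; intercept <- mean(yv)
    r2 <- 0; adj_r2 <- 0; fstat <- NA_real_; p <- 1
    slope_se <- NA_real_; intercept_se <- NA_real_
  } else {
    sigma2 <- rss / df_den
    slope_se <- sqrt(sigma2 / sxx)
    intercept_se <- sqrt(sigma2 * (1 / n + mean(xv)^2 / sxx))
    r2 <- 1 - rss / syy
    adj_r2 <- 1 - (1 - r2) * (n - 1) / df_den
    if (rss <= .Machine$double.eps * syy) {
      fstat <- Inf; p <- 0
    } else {
      fstat <- (syy - rss) / (rss / df_den)
      p <- stats::pf(fstat, 1, df_den, lower.tail = FALSE)
    }
  }
  structure(list(slope = slope, slope_se = slope_se, intercept = intercept,
                 intercept_se = intercept_se, r_squared = r2,
                 adjusted_r2 = adj_r2, f_statistic = fstat, df_num = 1L,
                 df_den = df_den, p_value = p, n = n,
                 x_name = x_name, y_name = y_name,
                 degenerate = degenerate,
                 data = tibble::tibble(x = xv, y = yv)),
            class = "flick_ols")
}

#' @export
print.flick_ols <- function(x, ...) {
  cat(sprintf("<flick_ols> %s ~ %s (n = %d)\n", x$y_name, x$x_name, x$n))
  cat(sprintf("  slope %.4g +- %.3g, intercept %.4g; adj R^2 %.3f\n",
              x$slope, x$slope_se, x$intercept, x$adjusted_r2))
  cat(sprintf("  F(%d, %d) = %.3g, p = %.3g%s\n", x$df_num, x$df_den,
              x$f_statistic, x$p_value,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

#' Tidy / glance methods for flick_ols fits
#'
#' @param x A `flick_ols` object.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`); `glance()`: one-row model summary.
#' @method tidy flick_ols
#' @export
tidy.flick_ols <- function(x, ...) {
  tstat <- c(x$intercept / x$intercept_se, x$slope / x$slope_se)
  tibble::tibble(
    term = c("(Intercept)", x$x_name),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    statistic = tstat,
    p.value = 2 * stats::pt(abs(tstat), df = x$df_den, lower.tail = FALSE)
  )
}

#' @rdname tidy.flick_ols
#' @method glance flick_ols
#' @export
glance.flick_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adjusted_r2,
                 statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df_num, df.residual = x$df_den, nobs = x$n)
}

#' 95% confidence interval for the OLS slope
#'
#' @param fit A `flick_ols`.
#' @param level Confidence level (default 0.95).
#' @return Numeric length-2: lower and upper bounds.
#' @export
slope_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "flick_ols"))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df_den)
  fit$slope + c(-1, 1) * tcrit * fit$slope_se
}

# negative profile log-likelihood of a trait under the OU tip correlation
# C(alpha); mean and variance profiled out by GLS.
ou_neg_loglik <- function(alpha, z, tree_s) {
  cm <- ou_corr_from_shared(tree_s, alpha)
  L <- tryCatch(chol(cm), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  n <- length(z)
  w <- backsolve(L, z, transpose = TRUE)
  w1 <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(w * w1) / sum(w1^2)
  r <- w - mu * w1
  s2 <- sum(r^2) / n
  if (s2 <= 0) return(1e10)
  n / 2 * log(s2) + sum(log(diag(L)))
}

# OU correlation from a normalized shared-time matrix (vcv / height)
ou_corr_from_shared <- function(s, alpha) {
  if (alpha < 1e-10) return(s)
  cm <- exp(-2 * alpha * (1 - s)) * (1 - exp(-2 * alpha * s)) /
    (1 - exp(-2 * alpha))
  diag(cm) <- 1
  cm
}

#' Phylogenetically corrected Pearson correlation under an OU model
#'
#' Estimates, for each trait separately, the strength of an
#' Ornstein--Uhlenbeck phylogenetic signal by maximising the marginal
#' Gaussian likelihood of the tip values given the OU-transformed tree
#' correlation (mean and variance profiled out by GLS), then whitens each
#' trait by the Cholesky factor of its fitted correlation and reports the
#' Pearson correlation of the whitened residuals. The p-value uses the
#' two-sided t-approximation with n - 2 degrees of freedom. On a star
#' phylogeny (no shared history) the estimate reduces exactly to the
#' ordinary Pearson correlation.
#'
#' @param tree A `phylo` object whose tip labels match `data[[species_col]]`.
#' @param data A data frame with one row per species.
#' @param x,y Bare column names of the two traits.
#' @param species_col Name of the species-id column (default
#'   `"species_id"`).
#' @param alpha_max Upper bound of the OU strength search, per unit tree
#'   height (default 50, effectively the star limit).
#' @return A `phylo_cor` object with `r`, `p_value`, `n`, `alpha_x`,
#'   `alpha_y` (fitted signal strengths) and `method`.
#' @export
phylo_pearson <- function(tree, data, x, y, species_col = "species_id",
                          alpha_max = 50) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(data))
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  sp <- data[[species_col]]
  if (is.null(sp)) stop("data lacks a '", species_col, "' column",
                        call. = FALSE)
  if (!setequal(sp, tree$tip.label) || anyDuplicated(sp))
    stop("species in data and tree tip labels must match one-to-one",
         call. = FALSE)
  ord <- match(tree$tip.label, sp)
  xv <- xv[ord]; yv <- yv[ord]
  n <- length(xv)
  if (n < 4L) stop("need at least 4 species", call. = FALSE)
  if (!all(is.finite(xv)) || !all(is.finite(yv)))
    stop("trait values must be finite", call. = FALSE)
  shared <- ape::vcv(tree)
  height <- max(diag(shared))
  s <- shared / height
  kappa <- kappa(s, exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop(sprintf("tree correlation matrix is numerically singular (condition number %.3g)",
                 kappa), call. = FALSE)

  fit_alpha <- function(z) {
    zc <- z - mean(z)
    if (sum(zc^2) == 0)
      return(list(alpha = alpha_max, corr = diag(n)))
    is_star <- all(abs(s[upper.tri(s)]) < 1e-12)
    if (is_star) return(list(alpha = 0, corr = s))
    opt <- stats::optimize(ou_neg_loglik, c(0, alpha_max), z = zc,
                           tree_s = s, tol = 1e-6)
    # compare against the Brownian boundary alpha = 0
    if (ou_neg_loglik(0, zc, s) <= opt$objective)
      opt <- list(minimum = 0, objective = ou_neg_loglik(0, zc, s))
    list(alpha = opt$minimum, corr = ou_corr_from_shared(s, opt$minimum))
  }
  fx <- fit_alpha(xv)
  fy <- fit_alpha(yv)
  whiten <- function(z, cm) {
    L <- chol(cm)
    w <- backsolve(L, z, transpose = TRUE)
    w1 <- backsolve(L, rep(1, n), transpose = TRUE)
    mu <- sum(w * w1) / sum(w1^2)
    w - mu * w1
  }
  ex <- whiten(xv, fx$corr)
  ey <- whiten(yv, fy$corr)
  denom <- sqrt(sum(ex^2) * sum(ey^2))
  if (denom <= 0) stop("a whitened trait has zero variance", call. = FALSE)
  r <- sum(ex * ey) / denom
  r <- max(-1, min(1, r))
  tstat <- if (abs(r) >= 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, p_value = p, n = n,
                 alpha_x = fx$alpha, alpha_y = fy$alpha,
                 x_name = x_name, y_name = y_name, method = "ou_gls"),
            class = "phylo_cor")
}

#' @export
print.phylo_cor <- function(x, ...) {
  cat(sprintf("<phylo_cor> %s ~ %s: r = %.3f, p = %.3g (n = %d)\n",
              x$x_name, x$y_name, x$r, x$p_value, x$n))
  cat(sprintf("  OU signal: alpha_x = %.3g, alpha_y = %.3g (per unit height)\n",
              x$alpha_x, x$alpha_y))
  invisible(x)
}

#' @rdname tidy.flick_ols
#' @method tidy phylo_cor
#' @export
tidy.phylo_cor <- function(x, ...) {
  obj <- x
  tibble::tibble(x = obj$x_name, y = obj$y_name, r = obj$r,
                 p.value = obj$p_value, n = obj$n, alpha_x = obj$alpha_x,
                 alpha_y = obj$alpha_y, method = obj$method)
}

#' Fit the study's statistical models to a synthetic dataset
#'
#' The two hypotheses and the trait-correlation structure: (1) OLS of
#' species-mean head angular speed on head MOI (expected negative: at
#' constant spring torque, heavier heads accelerate less); (2) OLS of
#' species-mean body angular displacement on relative MOI (expected
#' positive: angular-momentum balance); and phylogenetically corrected
#' Pearson correlations for the caudal--body, anal--dorsal and head--body
#' MOI pairs.
#'
#' @param study A `study_dataset` from [generate_study()] (or any list with
#'   `species` containing MOIs + mean kinematics, a `tree`, and per-surface
#'   MOIs in `moi`).
#' @return A `study_models` object: list with `ols_speed`,
#'   `ols_displacement` (class `flick_ols`) and `correlations` (list of
#'   `phylo_cor`).
#' @export
run_study_models <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  species <- study$species
  if (nrow(species) < 3L)
    stop("need at least 3 species to fit the study models", call. = FALSE)
  if (!all(c("mean_speed_degps", "mean_displacement_deg") %in%
             names(species)) || all(is.na(species$mean_speed_degps)))
    stop("study lacks per-species kinematics", call. = FALSE)
  ols_speed <- fit_ols(species, head_moi, mean_speed_degps)
  ols_disp <- fit_ols(species, relative_moi, mean_displacement_deg)
  surf_moi <- surface_moi_table(study)
  correlations <- list(
    caudal_body = phylo_pearson(study$tree, surf_moi, log_caudal, log_body),
    anal_dorsal = phylo_pearson(study$tree, surf_moi, log_anal, log_dorsal),
    head_body = phylo_pearson(study$tree, surf_moi, log_head, log_body)
  )
  structure(list(ols_speed = ols_speed, ols_displacement = ols_disp,
                 correlations = correlations, n_species = nrow(species)),
            class = "study_models")
}

# wide per-species table of log surface MOIs (logs: MOIs are strictly
# positive and span folds, the scale on which correlations are assessed)
surface_moi_table <- function(study) {
  rows <- lapply(study$moi, function(m) {
    get_moi <- function(nm) {
      v <- m$per_surface$moi_gcm2[m$per_surface$surface == nm]
      if (length(v) == 0L) NA_real_ else v
    }
    tibble::tibble(species_id = m$species_id,
                   log_head = log(m$head_moi),
                   log_body = log(get_moi("body")),
                   log_dorsal = log(get_moi("dorsal_fin")),
                   log_anal = log(get_moi("anal_fin")),
                   log_caudal = log(get_moi("caudal_fin")))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.study_models <- function(x, ...) {
  cat(sprintf("<study_models> %d species\n", x$n_species))
  cat("speed ~ head MOI:\n"); print(x$ols_speed)
  cat("displacement ~ relative MOI:\n"); print(x$ols_displacement)
  cat("phylogenetic correlations:\n")
  for (pc in x$correlations) print(pc)
  invisible(x)
}

#' @rdname tidy.flick_ols
#' @method tidy study_models
#' @export
tidy.study_models <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.flick_ols(x$ols_speed),
                  model = "speed_vs_head_moi", .before = 1L),
    dplyr::mutate(tidy.flick_ols(x$ols_displacement),
                  model = "displacement_vs_relative_moi", .before = 1L)
  )
}

#' @rdname tidy.flick_ols
#' @method glance study_models
#' @export
glance.study_models <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance.flick_ols(x$ols_speed),
                  model = "speed_vs_head_moi", .before = 1L),
    dplyr::mutate(glance.flick_ols(x$ols_displacement),
                  model = "displacement_vs_relative_moi", .before = 1L)
  )
}

#' Correlation table of a study_models fit
#'
#' @param x A `study_models`.
#' @return Tibble with one row per surface-pair correlation.
#' @export
correlation_table <- function(x) {
  stopifnot(inherits(x, "study_models"))
  dplyr::bind_rows(lapply(names(x$correlations), function(nm)
    dplyr::mutate(tidy.phylo_cor(x$correlations[[nm]]), pair = nm,
                  .before = 1L)))
}

#' Write a study_models report as JSON and CSV
#'
#' @param models A `study_models`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(models, dir) {
  stopifnot(inherits(models, "study_models"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tidy.study_models(models),
                   file.path(dir, "regression_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(glance.study_models(models),
                   file.path(dir, "regression_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(correlation_table(models),
                   file.path(dir, "phylo_correlations.csv"),
                   row.names = FALSE)
  report <- list(
    regressions = glance.study_models(models),
    coefficients = tidy.study_models(models),
    correlations = correlation_table(models)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
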