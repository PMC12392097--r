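test_that("closed-form OLS matches exact lines and hand calculations", {
  d <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
  fit <- fit_ols(d, x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$adjusted_r2, 1)
  # normal equations by hand: slope = 3/2
  d2 <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4))
  expect_equal(fit_ols(d2, x, y)$slope, 1.5)
})

test_that("OLS agrees with lm() to near machine precision", {
  set.seed(8)
  for (i in 1:5) {
    d <- data.frame(x = stats::rnorm(17, 2500, 400))
    d$y <- 1200 - 0.15 * d$x + stats::rnorm(17, 0, 40)
    fit <- fit_ols(d, x, y)
    ref <- stats::lm(y ~ x, data = d)
    sm <- summary(ref)
    expect_equal(fit$slope, unname(stats::coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(stats::coef(ref)[1]),
                 tolerance = 1e-10)
    expect_equal(fit$slope_se, sm$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(fit$adjusted_r2, sm$adj.r.squared, tolerance = 1e-10)
    expect_equal(fit$f_statistic, unname(sm$fstatistic[1]),
                 tolerance = 1e-10)
    expect_equal(fit$p_value, sm$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("OLS agrees with a brute-force least-squares minimizer", {
  set.seed(15)
  d <- data.frame(x = stats::runif(12, 0, 10))
  d$y <- 3 - 0.7 * d$x + stats::rnorm(12, 0, 0.5)
  fit <- fit_ols(d, x, y)
  rss <- function(par) sum((d$y - par[1] - par[2] * d$x)^2)
  opt <- stats::optim(c(0, 0), rss, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit$intercept, opt$par[1], tolerance = 1e-6)
  expect_equal(fit$slope, opt$par[2], tolerance = 1e-6)
})

test_that("degenerate regressions follow the documented policy", {
  expect_error(fit_ols(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(fit_ols(data.frame(x = 1:2, y = 1:2), x, y), "at least 3")
  flat <- fit_ols(data.frame(x = 1:6, y = rep(2, 6)), x, y)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  expect_true(is.na(flat$f_statistic))
  expect_true(flat$degenerate)
})

test_that("tidy and glance expose broom-style summaries", {
  d <- data.frame(x = 1:6, y = c(1.1, 2.3, 2.8, 4.1, 5.2, 5.9))
  fit <- fit_ols(d, x, y)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$adj.r.squared, fit$adjusted_r2)
  expect_equal(gl$nobs, 6L)
  ci <- slope_confint(fit)
  expect_lt(ci[1], fit$slope)
  expect_gt(ci[2], fit$slope)
})

test_that("phylo correlation reduces to Pearson on a star tree", {
  st <- star_tree(15)
  set.seed(3)
  d <- data.frame(species_id = st$tip.label, a = stats::rnorm(15),
                  b = stats::rnorm(15))
  pc <- phylo_pearson(st, d, a, b)
  expect_equal(pc$r, stats::cor(d$a, d$b), tolerance = 1e-6)
  expect_equal(pc$p_value, stats::cor.test(d$a, d$b)$p.value,
               tolerance = 1e-6)
})

test_that("identical traits give r = 1 and mismatches are rejected", {
  tree <- generate_phylogeny(10, seed = 6)
  d <- data.frame(species_id = tree$tip.label, a = stats::rnorm(10))
  d$b <- d$a
  pc <- phylo_pearson(tree, d, a, b)
  expect_equal(pc$r, 1, tolerance = 1e-9)
  d_bad <- d; d_bad$species_id[1] <- "missing"
  expect_error(phylo_pearson(tree, d_bad, a, b), "one-to-one")
  expect_error(phylo_pearson(tree, d[1:3, ], a, b))
})

test_that("phylo correlation recovers a known Brownian cross-correlation", {
  set.seed(44)
  rs <- replicate(40, {
    tree <- generate_phylogeny(100, seed = NULL)
    d <- simulate_bm_pair(tree, 0.7)
    c(phylo_pearson(tree, d, a, b)$r, stats::cor(d$a, d$b))
  })
  expect_equal(mean(rs[1, ]), 0.7, tolerance = 0.05)
  # naive Pearson has visibly inflated sampling variance on trees
  expect_gt(stats::sd(rs[2, ]), 1.5 * stats::sd(rs[1, ]))
})

test_that("whitening by the true covariance standardises the residuals", {
  tree <- generate_phylogeny(80, seed = 10)
  L <- t(chol(ou_tip_correlation(tree, 0)))
  set.seed(12)
  vars <- replicate(80, {
    z <- as.numeric(L %*% stats::rnorm(80))
    w <- backsolve(chol(ou_tip_correlation(tree, 0)), z, transpose = TRUE)
    stats::var(w)
  })
  expect_equal(mean(vars), 1, tolerance = 0.1)
})

test_that("type-I error is controlled on a deep imbalanced tree", {
  tree <- caterpillar_tree(32)
  L <- t(chol(ou_tip_correlation(tree, 0)))
  set.seed(77)
  pvals <- replicate(200, {
    d <- data.frame(species_id = tree$tip.label,
                    a = as.numeric(L %*% stats::rnorm(32)),
                    b = as.numeric(L %*% stats::rnorm(32)))
    c(phylo_pearson(tree, d, a, b)$p_value,
      stats::cor.test(d$a, d$b)$p.value)
  })
  expect_lt(mean(pvals[1, ] < 0.05), 0.12)  # corrected: near nominal
  expect_gt(mean(pvals[2, ] < 0.05), 0.10)  # naive: visibly inflated
})

test_that("the study models report the hypothesised structure", {
  st <- generate_study(trait_config(n_species = 6), seed = 21,
                       trials_range = c(2L, 2L), dt = 5e-5,
                       keep_trials = FALSE)
  mod <- run_study_models(st)
  expect_s3_class(mod$ols_speed, "flick_ols")
  expect_s3_class(mod$ols_displacement, "flick_ols")
  expect_named(mod$correlations, c("caudal_body", "anal_dorsal", "head_body"))
  expect_lt(mod$ols_speed$slope, 0)
  expect_gt(mod$ols_displacement$slope, 0)
  tab <- correlation_table(mod)
  expect_equal(nrow(tab), 3L)
  expect_true(all(abs(tab$r) <= 1))
  # single-species studies cannot be fit
  st1 <- st; st1$species <- st1$species[1, ]
  expect_error(run_study_models(st1), "at least 3")
})

test_that("a drag-free noiseless study recovers the exact balance slope", {
  st <- generate_study(trait_config(n_species = 5), seed = 9,
                       trials_range = c(1L, 1L), torque_cv = 0,
                       drag_scale_head = 0, drag_scale_body = 0,
                       sigma_noise = 0, dt = 2e-5, keep_trials = FALSE)
  mod <- run_study_models(st)
  # displacement = relative MOI x 45 exactly, so the OLS line is y = 45 x
  expect_equal(mod$ols_displacement$slope, 45, tolerance = 1e-3)
  expect_equal(mod$ols_displacement$adjusted_r2, 1, tolerance = 1e-6)
})

test_that("report files are written in both formats", {
  st <- generate_study(trait_config(n_species = 5), seed = 13,
                       trials_range = c(1L, 1L), dt = 5e-5,
                       keep_trials = FALSE)
  mod <- run_study_models(st)
  dir <- withr::local_tempdir()
  write_report(mod, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "phylo_correlations.csv")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(rep$correlations), 3L)
})
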