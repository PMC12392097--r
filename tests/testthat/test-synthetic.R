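test_that("pure-birth phylogenies are ultrametric, unit height, seeded", {
  expect_error(generate_phylogeny(2), "at least 3")
  t1 <- generate_phylogeny(17, seed = 5)
  t2 <- generate_phylogeny(17, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))
  depths <- ape::node.depth.edgelength(t1)[1:17]
  expect_equal(depths, rep(1, 17), tolerance = 1e-9)
  t3 <- generate_phylogeny(3, seed = 2)
  expect_equal(ape::Ntip(t3), 3L)
  expect_true(ape::is.binary(t3))
})

test_that("the three unrooted quartet topologies are equally likely", {
  # Yule-process label exchangeability: each split of {a,b,c,d} into sister
  # pairs has probability 1/3
  set.seed(20)
  split_of <- function(tree) {
    # any 2-tip cherry fixes the unrooted split ab|cd; report sp01's partner
    tip_edges <- tree$edge[tree$edge[, 2] <= 4L, ]
    parents <- table(tip_edges[, 1])
    cherry_parent <- as.integer(names(parents)[parents == 2][1])
    pair <- tree$tip.label[tip_edges[tip_edges[, 1] == cherry_parent, 2]]
    if ("sp01" %in% pair) setdiff(pair, "sp01")
    else setdiff(tree$tip.label, c(pair, "sp01"))[1]
  }
  splits <- vapply(1:500, function(i) split_of(generate_phylogeny(4)),
                   character(1))
  freq <- table(factor(splits, levels = c("sp02", "sp03", "sp04"))) / 500
  expect_true(all(abs(freq - 1 / 3) < 0.06))
})

test_that("OU tip correlations interpolate Brownian and star limits", {
  tree <- generate_phylogeny(10, seed = 3)
  shared <- ape::vcv(tree) / max(diag(ape::vcv(tree)))
  bm <- ou_tip_correlation(tree, 0)
  expect_equal(unname(bm), unname(shared), tolerance = 1e-12)
  strong <- ou_tip_correlation(tree, 200)
  off <- strong[upper.tri(strong)]
  expect_lt(max(abs(off)), 1e-4)
  expect_equal(diag(strong), rep(1, 10), ignore_attr = TRUE)
  st <- star_tree(6)
  expect_equal(unname(ou_tip_correlation(st, 1)), diag(6), tolerance = 1e-12)
})

test_that("trait simulation is seeded and respects the star-tree iid limit", {
  cfg <- trait_config(n_species = 8, seed = 11)
  tree <- generate_phylogeny(8, seed = 4)
  a <- simulate_traits(tree, cfg)
  b <- simulate_traits(tree, cfg)
  expect_identical(a, b)
  # star tree + Brownian: tips are iid with the configured cross-correlation
  st <- star_tree(60)
  cfg0 <- trait_config(n_species = 60, ou_alpha = 0)
  set.seed(9)
  cors <- replicate(60, {
    tr <- simulate_traits(st, cfg0)
    cor(tr$dorsal_size, tr$anal_size)
  })
  expect_equal(mean(cors), 0.9, tolerance = 0.05)
})

test_that("configured cross-trait correlations are recovered on large trees", {
  tree <- generate_phylogeny(100, seed = 8)
  cfg <- trait_config(n_species = 100, ou_alpha = 1)
  set.seed(14)
  cors <- replicate(120, {
    tr <- simulate_traits(tree, cfg)
    d <- data.frame(species_id = tr$species_id, a = tr$dorsal_size,
                    b = tr$anal_size)
    phylo_pearson(tree, d, a, b)$r
  })
  expect_equal(mean(cors), 0.9, tolerance = 0.05)
})

test_that("a non-positive-definite correlation matrix is rejected", {
  bad <- diag(6); bad[1, 2] <- bad[2, 1] <- 1.2
  dimnames(bad) <- list(trait_names(), trait_names())
  expect_error(trait_config(correlation = bad), "positive definite")
})

test_that("silhouettes normalise head area and map traits monotonically", {
  set.seed(2)
  for (i in 1:5) {
    z <- stats::setNames(as.list(stats::rnorm(6)), trait_names())
    m <- build_silhouette(c(list(species_id = "t"), z))
    expect_equal(polygon_area(m$surfaces$head$vertices), 30,
                 tolerance = 1e-3)
  }
  base <- stats::setNames(as.list(rep(0, 6)), trait_names())
  lo <- c(list(species_id = "lo"), base); lo$head_moi_shape <- -1
  hi <- c(list(species_id = "hi"), base); hi$head_moi_shape <- 1
  s_lo <- summarize_model(build_silhouette(lo))
  s_hi <- summarize_model(build_silhouette(hi))
  # same projected area, different MOI: the study's design principle
  expect_equal(polygon_area(build_silhouette(lo)$surfaces$head$vertices),
               polygon_area(build_silhouette(hi)$surfaces$head$vertices))
  expect_lt(s_lo$head_moi, s_hi$head_moi)
  # deeper bodies have larger body MOI
  shallow <- c(list(species_id = "s"), base); shallow$body_depth <- -1
  deep <- c(list(species_id = "d"), base); deep$body_depth <- 1
  moi_of_body <- function(m) {
    s <- summarize_model(m)
    s$per_surface$moi_gcm2[s$per_surface$surface == "body"]
  }
  expect_lt(moi_of_body(build_silhouette(shallow)),
            moi_of_body(build_silhouette(deep)))
})

test_that("shifting head mass toward the hinge lowers the head MOI", {
  # lower taper = deeper base at the hinge, shallower snout, at fixed area
  moi_at_taper <- function(tp) {
    v <- head_polygon(30, 12, tp)
    compute_moi(decompose_strips(v, axis_line(c(0, 0)), 0.1,
                                 areal_density = 1.44))
  }
  tapers <- c(0.3, 0.55, 0.9, 1.4)
  mois <- vapply(tapers, moi_at_taper, numeric(1))
  expect_true(all(diff(mois) > 0))
})

test_that("a finless model collapses lateral MOI onto the body", {
  m <- toy_model()
  s <- summarize_model(m)
  expect_equal(s$contributions$fraction, 1)
  expect_equal(s$lateral_moi,
               s$per_surface$moi_gcm2[s$per_surface$surface == "body"])
})

test_that("small studies are reproducible and structurally complete", {
  st1 <- generate_study(trait_config(n_species = 5), seed = 33,
                        trials_range = c(2L, 3L), dt = 5e-5,
                        keep_trials = FALSE)
  st2 <- generate_study(trait_config(n_species = 5), seed = 33,
                        trials_range = c(2L, 3L), dt = 5e-5,
                        keep_trials = FALSE)
  expect_identical(st1$species, st2$species)
  expect_identical(ape::write.tree(st1$tree), ape::write.tree(st2$tree))
  n_tr <- st1$species$n_trials
  expect_true(all(n_tr >= 2 & n_tr <= 3))
  expect_equal(nrow(st1$species), 5L)
  expect_true(all(c("head_moi", "lateral_moi", "relative_moi",
                    "mean_speed_degps", "mean_displacement_deg")
                  %in% names(st1$species)))
})

test_that("default-calibration models are body-dominant with plausible MOIs", {
  st <- generate_study(trait_config(n_species = 6), seed = 7,
                       trials_range = c(1L, 1L), dt = 5e-5,
                       keep_trials = FALSE)
  expect_true(all(st$species$head_moi >= 1969 & st$species$head_moi <= 3534))
  for (m in st$moi) {
    body_frac <- m$contributions$fraction[m$contributions$surface == "body"]
    expect_true(all(body_frac >
                      m$contributions$fraction[m$contributions$surface !=
                                                 "body"]))
    # pelvic fin contributes very little relative to the lateral profile
    expect_lt(m$pelvic_moi / m$lateral_moi, 0.1)
  }
})

test_that("study directories contain every artifact", {
  st <- generate_study(trait_config(n_species = 4), seed = 3,
                       trials_range = c(1L, 2L), dt = 5e-5)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "phylogeny.nwk")))
  expect_true(file.exists(file.path(dir, "traits.csv")))
  expect_true(file.exists(file.path(dir, "moi.csv")))
  expect_true(file.exists(file.path(dir, "species.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(length(list.files(file.path(dir, "silhouettes"))), 4L)
  expect_gt(length(list.files(file.path(dir, "trials"), pattern = "csv$")), 0)
  tree <- ape::read.tree(file.path(dir, "phylogeny.nwk"))
  expect_equal(sort(tree$tip.label), sort(st$traits$species_id))
})
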