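rect_axis <- axis_line(c(0, 0), c(0, 1))
rect10x3 <- cbind(c(0, 10, 10, 0), c(0, 0, 3, 3))

test_that("a rectangle on the axis partitions into uniform strips", {
  d <- decompose_strips(rect10x3, rect_axis, 1, areal_density = 1.44)
  expect_equal(nrow(d$strips), 10)
  expect_equal(d$strips$area_cm2, rep(3, 10))
  expect_equal(sort(d$strips$r_cm), seq(0.5, 9.5, by = 1))
  expect_equal(d$strips$mass_g, d$strips$area_cm2 * 1.44)
})

test_that("a strip wider than the polygon gives one band at the centroid", {
  d <- decompose_strips(rect10x3, rect_axis, 50, areal_density = 1)
  expect_equal(nrow(d$strips), 1)
  expect_equal(d$strips$area_cm2, 30)
  expect_equal(d$strips$r_cm, 5) # centroid distance from the y axis
})

test_that("right-triangle strips equal the exact trapezoid clip areas", {
  # legs: 4 cm along the axis, 6 cm perpendicular; height at distance u from
  # the axis is 4 * (1 - u/6), so band k covers the exact trapezoid area
  tri <- cbind(c(0, 6, 0), c(0, 0, 4))
  d <- decompose_strips(tri, rect_axis, 1, areal_density = 1)
  h <- function(u) 4 * (1 - u / 6)
  expected <- vapply(0:5, function(k)
    (h(k) + h(k + 1)) / 2, numeric(1))
  expect_equal(nrow(d$strips), 6)
  areas_by_r <- d$strips$area_cm2[order(d$strips$r_cm)]
  expect_equal(areas_by_r, expected, tolerance = 1e-12)
  expect_equal(sum(d$strips$area_cm2), 12, tolerance = 1e-12)
})

test_that("strip areas conserve polygon area to 1e-6 relative", {
  set.seed(7)
  for (i in 1:10) {
    poly <- random_convex_polygon(9, radius = 4, center = c(2, 1))
    for (w in c(0.5, 0.7, 1.3)) {
      d <- decompose_strips(poly, rect_axis, w, areal_density = 1)
      expect_equal(sum(d$strips$area_cm2), polygon_area(poly),
                   tolerance = 1e-6)
    }
  }
})

test_that("compute_moi applies I = sum m r^2", {
  one <- tibble::tibble(r_cm = 2, area_cm2 = 5, mass_g = 5 * 1.44)
  expect_equal(compute_moi(one), 28.8)
  expect_equal(compute_moi(one[0, ]), 0)
})

test_that("strip-sum MOI matches the thin-plate closed form", {
  # 10 x 3 plate about an edge: rho h L^3 / 3 = 1440 g cm^2
  d <- decompose_strips(rect10x3, rect_axis, 0.1, areal_density = 1.44)
  expect_equal(compute_moi(d), 1440, tolerance = 0.005)
})

test_that("strip-sum error shrinks quadratically as widths halve", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(w) {
    abs(compute_moi(decompose_strips(rect10x3, rect_axis, w,
                                     areal_density = 1.44)) - 1440)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  order21 <- log2(errs[1] / errs[2])
  expect_gte(order21, 1.9)
  # against the pixel oracle at 10x finer resolution, halving the strip width
  # reduces the error for irregular polygons too
  set.seed(21)
  for (i in 1:3) {
    poly <- random_convex_polygon(8, radius = 3, center = c(4, 0))
    oracle <- exact_moi_about_x(poly, x0 = 0, density = 1)
    e <- vapply(c(0.8, 0.4, 0.2), function(w)
      abs(compute_moi(decompose_strips(poly, rect_axis, w,
                                       areal_density = 1)) - oracle),
      numeric(1))
    expect_lt(e[2], e[1])
    expect_lt(e[3], e[2])
  }
})

test_that("pixel oracle reproduces the analytic plate MOI", {
  ras <- rasterize_polygon(rect10x3, 0.01)
  expect_equal(pixel_oracle_moi(ras, rect_axis, areal_density = 1.44), 1440,
               tolerance = 0.005)
  empty <- matrix(FALSE, 5, 5)
  expect_warning(out <- pixel_oracle_moi(empty, rect_axis, resolution = 0.1),
                 "no foreground")
  expect_equal(out, 0)
})

test_that("strip engine and pixel oracle agree on random convex polygons", {
  set.seed(99)
  for (i in 1:6) {
    poly <- random_convex_polygon(8, radius = 2.5,
                                  center = stats::runif(2, 1, 3))
    strip <- compute_moi(decompose_strips(poly, rect_axis, 0.05,
                                          areal_density = 1.44))
    pix <- pixel_oracle_moi(rasterize_polygon(poly, 0.02), rect_axis,
                            areal_density = 1.44)
    expect_equal(strip, pix, tolerance = 0.01)
  }
})

test_that("parallel-axis theorem holds within 0.5% at default widths", {
  set.seed(5)
  for (i in 1:5) {
    poly <- random_convex_polygon(9, radius = 3, center = c(0, 0))
    cen <- polygon_centroid(poly)
    axis_c <- axis_line(cen, c(0, 1))
    d_off <- 4.2
    axis_d <- axis_line(cen + c(d_off, 0), c(0, 1))
    i_c <- compute_moi(decompose_strips(poly, axis_c, 0.5, areal_density = 1.44))
    i_d <- compute_moi(decompose_strips(poly, axis_d, 0.5, areal_density = 1.44))
    mass <- polygon_area(poly) * 1.44
    expect_equal(i_d, i_c + mass * d_off^2, tolerance = 0.005)
  }
})

test_that("uniform scaling by s multiplies MOI by s^4", {
  set.seed(13)
  for (s in c(0.5, 2, 3.7)) {
    poly <- random_convex_polygon(8, radius = 2, center = c(3, 1))
    base <- compute_moi(decompose_strips(poly, rect_axis, 0.05,
                                         areal_density = 1))
    scaled <- compute_moi(decompose_strips(poly * s, rect_axis, 0.05 * s,
                                           areal_density = 1))
    expect_equal(scaled, base * s^4, tolerance = 1e-6)
  }
})

test_that("the rectangle (hand-measurement) mode approximates the exact mode", {
  d_rect <- decompose_strips(rect10x3, rect_axis, 0.5,
                             areal_density = 1.44, method = "rectangle")
  d_ex <- decompose_strips(rect10x3, rect_axis, 0.5, areal_density = 1.44)
  # on an axis-aligned rectangle the two decompositions coincide in area
  expect_equal(sum(d_rect$strips$area_cm2), sum(d_ex$strips$area_cm2))
  tri <- cbind(c(0, 6, 0), c(0, 0, 4))
  m_rect <- compute_moi(decompose_strips(tri, rect_axis, 0.2,
                                         areal_density = 1,
                                         method = "rectangle"))
  expect_equal(m_rect, exact_moi_about_x(tri), tolerance = 0.01)
})

test_that("decompose_strips validates its input", {
  expect_error(decompose_strips(rect10x3, rect_axis, 0, areal_density = 1),
               "strip_width")
  expect_error(decompose_strips(rect10x3, rect_axis, -1, areal_density = 1),
               "strip_width")
  expect_error(decompose_strips(cbind(c(0, 1, 2), c(0, 1, 2)), rect_axis, 1,
                                areal_density = 1), "degenerate")
  expect_error(decompose_strips(rect10x3, rect_axis, 1), "areal_density")
})

test_that("summarize_model reports axes, lateral sum and contributions", {
  m <- toy_model() # head + body only
  s <- summarize_model(m)
  expect_equal(s$contributions$surface, "body")
  expect_equal(s$contributions$fraction, 1)
  expect_equal(s$lateral_moi,
               s$per_surface$moi_gcm2[s$per_surface$surface == "body"])
  expect_equal(s$pelvic_moi, 0)
  # head about hinge (x = 0): 10 x 3 plate about its edge
  expect_equal(s$head_moi, 1440, tolerance = 0.005)
  expect_gt(s$relative_moi, 0)
  expect_equal(s$relative_moi, s$head_moi / s$lateral_moi)
})

test_that("relative MOI is a plain ratio and contributions sum to one", {
  m <- reference_model()
  s <- summarize_model(m)
  expect_equal(sum(s$contributions$fraction), 1, tolerance = 1e-9)
  expect_equal(s$relative_moi, s$head_moi / s$lateral_moi)
  expect_equal(2000 / 400000, 0.005) # the ratio convention used throughout
})

test_that("fish_model validation catches malformed models", {
  head <- control_surface("head",
                          cbind(c(0, 0, -10, -10), c(-1.5, 1.5, 1.5, -1.5)),
                          1.44)
  body <- control_surface("body", cbind(c(0, 40, 40, 0), c(-5, -5, 5, 5)),
                          1.44)
  expect_error(fish_model("x", list(head, head), c(0, 0)), "duplicate")
  expect_error(fish_model("x", list(body), c(0, 0)), "exactly one")
  expect_error(fish_model("x", list(head, body), c(200, 0)), "hinge_point")
  expect_error(fish_model("x", list(head, body), c(0, 0),
                          head_area_target = 50), "head area")
})

test_that("silhouette JSON round-trips a model", {
  m <- reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_silhouette_json(m, path)
  m2 <- read_silhouette_json(path)
  expect_equal(m2$species_id, m$species_id)
  expect_equal(m2$hinge_point, m$hinge_point)
  expect_equal(m2$com_point, m$com_point, tolerance = 1e-12)
  s1 <- summarize_model(m); s2 <- summarize_model(m2)
  expect_equal(s2$head_moi, s1$head_moi, tolerance = 1e-12)
  expect_equal(s2$lateral_moi, s1$lateral_moi, tolerance = 1e-12)
})

test_that("moi results tidy into the CSV layout", {
  tab <- tidy(summarize_model(reference_model()))
  expect_true(all(c("species_id", "surface", "moi_gcm2", "head_moi",
                    "lateral_moi", "relative_moi", "contribution_fraction")
                  %in% names(tab)))
  expect_equal(nrow(tab), 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_moi_csv(summarize_model(reference_model()), path)
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.csv(path)), 6)
})
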