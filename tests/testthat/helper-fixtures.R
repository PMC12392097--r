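# Fixtures and independent oracles shared across the suite.

# random convex polygon: convex hull of points on a jittered circle
random_convex_polygon <- function(n = 8, radius = 3, center = c(0, 0)) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * stats::runif(n, 0.5, 1)
  pts <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]
}

# Exact moment of inertia of a polygon plate about the vertical line x = x0,
# by the closed-form shoelace integral of x^2 dA (independent of the strip
# decomposition): integral x^2 dA =
#   (1/12) * sum (x_i^2 + x_i x_j + x_j^2) (x_i y_j - x_j y_i).
exact_moi_about_x <- function(vertices, x0 = 0, density = 1) {
  v <- as.matrix(vertices)
  x <- v[, 1] - x0; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  ix <- sum((x^2 + x * x[j] + x[j]^2) * cross) / 12
  density * abs(ix)
}

# ultrametric caterpillar tree of height 1 with evenly spaced splits
caterpillar_tree <- function(n) {
  s <- seq(0, 1, length.out = n)[-1]
  nwk <- sprintf("(sp01:%.12f,sp02:%.12f)", s[1], s[1])
  for (k in 3:n)
    nwk <- sprintf("(%s:%.12f,sp%02d:%.12f)", nwk, s[k - 1] - s[k - 2], k,
                   s[k - 1])
  ape::read.tree(text = paste0(nwk, ";"))
}

# star tree (all tips attached to the root at height 1)
star_tree <- function(n) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("sp%02d:1", seq_len(n)), collapse = ","), ");"))
}

# simulate Brownian traits with a given cross-correlation on a tree
simulate_bm_pair <- function(tree, rho) {
  n <- length(tree$tip.label)
  L <- t(chol(ou_tip_correlation(tree, 0)))
  z <- matrix(stats::rnorm(2 * n), n, 2) %*%
    chol(matrix(c(1, rho, rho, 1), 2))
  data.frame(species_id = tree$tip.label,
             a = as.numeric(L %*% z[, 1]),
             b = as.numeric(L %*% z[, 2]))
}

# a tiny two-surface model (rectangular head and body) for simulator tests
toy_model <- function() {
  head <- control_surface("head",
                          cbind(c(0, 0, -10, -10), c(-1.5, 1.5, 1.5, -1.5)),
                          1.44)
  body <- control_surface("body",
                          cbind(c(0, 40, 40, 0), c(-5, -5, 5, 5)), 1.44)
  fish_model("toy", list(head, body), hinge_point = c(0, 0),
             head_area_target = 30)
}
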