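#' Simulate a pure-birth study phylogeny
#'
#' Desk-scale stand-in for a pruned, time-calibrated published tree: a Yule
#' (pure-birth) tree with `n_species` tips, rescaled to unit height so that
#' all root-to-tip paths equal 1 (ultrametric). Tip labels are `sp01`,
#' `sp02`, ... Deterministic under `seed`.
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
generate_phylogeny <- function(n_species, seed = NULL) {
  if (!is.numeric(n_species) || n_species < 3)
    stop("n_species must be at least 3", call. = FALSE)
  n_species <- as.integer(n_species)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_species)])
  tree$edge.length <- tree$edge.length / height
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Tip correlation matrix of an Ornstein--Uhlenbeck process on a tree
#'
#' Root-conditioned OU on an ultrametric tree of height T: two tips sharing
#' time `t` have correlation
#' `exp(-2a (T - t)) * (1 - exp(-2a t)) / (1 - exp(-2a T))`
#' (unit diagonal). The limit `a -> 0` is Brownian motion (`t / T`); large
#' `a` decorrelates the tips (star limit). `alpha` is expressed per unit of
#' tree height.
#'
#' @param tree A `phylo` object (ultrametric; a star tree is allowed).
#' @param alpha OU selection strength, >= 0 (0 = Brownian motion).
#' @return A symmetric positive-definite correlation matrix with rows/columns
#'   in `tree$tip.label` order.
#' @export
ou_tip_correlation <- function(tree, alpha) {
  stopifnot(inherits(tree, "phylo"), is.numeric(alpha), length(alpha) == 1L,
            alpha >= 0, is.finite(alpha))
  shared <- ape::vcv(tree)
  height <- max(diag(shared))
  if (height <= 0) stop("tree has zero height", call. = FALSE)
  s <- shared / height # shared time fraction in [0, 1]
  if (alpha < 1e-10) return(s / max(diag(s)))
  a <- alpha
  cm <- exp(-2 * a * (1 - s)) * (1 - exp(-2 * a * s)) / (1 - exp(-2 * a))
  diag(cm) <- 1
  cm
}

#' Default configuration for the correlated-trait generator
#'
#' Log-scale means, standard deviations, OU strengths and a cross-trait
#' correlation matrix for the six silhouette traits. The defaults encode the
#' study conditions the statistical layer assumes: head and body shape traits
#' are moderately correlated, the dorsal and anal fins strongly so, and the
#' caudal fin tracks the body.
#'
#' @param n_species Number of species (default 17).
#' @param trait_sd Common log-scale standard deviation (default 1: traits are
#'   standardized deviations, mapped to geometry by [build_silhouette()]).
#' @param ou_alpha Common OU strength per unit tree height (default 1,
#'   moderate mean reversion; 0 gives Brownian motion).
#' @param correlation Optional 6 x 6 correlation matrix overriding the
#'   default (rows/cols in `trait_names()` order).
#' @param seed Integer seed for trait simulation.
#' @return A `trait_config` list.
#' @export
trait_config <- function(n_species = 17, trait_sd = 1, ou_alpha = 1,
                         correlation = NULL, seed = NULL) {
  nms <- trait_names()
  p <- length(nms)
  if (is.null(correlation)) {
    correlation <- diag(p)
    dimnames(correlation) <- list(nms, nms)
    set_cor <- function(a, b, r) {
      correlation[a, b] <<- r; correlation[b, a] <<- r
    }
    set_cor("head_moi_shape", "body_depth", 0.5)
    set_cor("body_depth", "caudal_size", 0.7)
    set_cor("dorsal_size", "anal_size", 0.9)
    set_cor("body_depth", "dorsal_size", 0.3)
    set_cor("body_depth", "anal_size", 0.3)
    set_cor("body_depth", "pelvic_size", 0.2)
    set_cor("caudal_size", "dorsal_size", 0.25)
    set_cor("caudal_size", "anal_size", 0.25)
    set_cor("head_moi_shape", "caudal_size", 0.3)
  }
  stopifnot(is.matrix(correlation), nrow(correlation) == p,
            ncol(correlation) == p,
            isTRUE(all.equal(correlation, t(correlation))),
            all(diag(correlation) == 1))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("trait correlation matrix is not positive definite", call. = FALSE)
  stopifnot(n_species >= 3, trait_sd > 0, all(ou_alpha >= 0))
  if (length(ou_alpha) == 1L) ou_alpha <- rep(ou_alpha, p)
  stopifnot(length(ou_alpha) == p)
  if (length(trait_sd) == 1L) trait_sd <- rep(trait_sd, p)
  stopifnot(length(trait_sd) == p, all(trait_sd > 0))
  structure(list(n_species = as.integer(n_species),
                 trait_names = nms,
                 trait_sd = stats::setNames(trait_sd, nms),
                 ou_alpha = stats::setNames(ou_alpha, nms),
                 correlation = correlation, seed = seed),
            class = "trait_config")
}

#' Names of the silhouette traits
#' @return Character vector of the six trait names.
#' @export
trait_names <- function() {
  c("head_moi_shape", "body_depth", "caudal_size", "dorsal_size",
    "anal_size", "pelvic_size")
}

#' Simulate correlated trait evolution along a phylogeny
#'
#' Draws tip values for the configured traits under a (root-conditioned) OU
#' process per trait with a cross-trait correlation matrix: rows of a
#' standard-normal matrix receive the cross-trait correlation, then each
#' trait column is given its own tree-induced structure via the Cholesky
#' factor of [ou_tip_correlation()]. With equal OU strengths this is exactly
#' the Kronecker (tree x trait) covariance model; with unequal strengths it
#' is the natural per-trait generalisation. Values are standardized
#' (zero mean, unit stationary variance) deviations scaled by `trait_sd`.
#'
#' @param tree A `phylo` object.
#' @param config A [trait_config()].
#' @return A tibble: `species_id` plus one column per trait (standardized
#'   log-scale deviations).
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "trait_config"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("tree must have at least 3 tips", call. = FALSE)
  p <- length(config$trait_names)
  Rchol <- chol(config$correlation)
  draw <- function() {
    z <- matrix(stats::rnorm(n * p), n, p) %*% Rchol
    y <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      cj <- ou_tip_correlation(tree, config$ou_alpha[[j]])
      y[, j] <- as.numeric(t(chol(cj)) %*% z[, j]) * config$trait_sd[[j]]
    }
    y
  }
  y <- with_seed(config$seed, draw())
  colnames(y) <- config$trait_names
  dplyr::bind_cols(tibble::tibble(species_id = tree$tip.label),
                   tibble::as_tibble(y))
}
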