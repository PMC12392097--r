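#' Control-surface names recognised in a fish model
#' @keywords internal
SURFACE_NAMES <- c("head", "body", "dorsal_fin", "anal_fin", "caudal_fin",
                   "pelvic_fin")

#' Surfaces whose combined moment of inertia forms the lateral MOI
#' (body plus median fins; the pelvic fin is reported separately)
#' @keywords internal
LATERAL_SURFACES <- c("body", "dorsal_fin", "anal_fin", "caudal_fin")

#' Default areal densities (g/cm^2): 4 mm foamed PVC for head and body,
#' thinner sheet for the fins.
#' @keywords internal
DEFAULT_DENSITIES <- c(head = 1.44, body = 1.44, dorsal_fin = 0.475,
                       anal_fin = 0.475, caudal_fin = 0.475,
                       pelvic_fin = 0.475)

#' Construct a control surface
#'
#' A named planar polygon with a material areal density. Surfaces are the
#' morphological units whose moments of inertia the package computes: the
#' head, the body, and up to four fins.
#'
#' @param name One of `"head"`, `"body"`, `"dorsal_fin"`, `"anal_fin"`,
#'   `"caudal_fin"`, `"pelvic_fin"`.
#' @param vertices An n x 2 matrix or data frame with `x`/`y` columns (cm),
#'   forming a simple polygon with positive area.
#' @param areal_density Mass per unit projected area, g/cm^2.
#' @return A `control_surface` object.
#' @examples
#' control_surface("head", cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)), 1.44)
#' @export
control_surface <- function(name, vertices,
                            areal_density = DEFAULT_DENSITIES[[name]]) {
  name <- match.arg(name, SURFACE_NAMES)
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3L || !all(is.finite(v)))
    stop("surface '", name, "': vertices must be >= 3 finite points",
         call. = FALSE)
  if (polygon_area(v) <= 0)
    stop("surface '", name, "': polygon has zero area", call. = FALSE)
  if (!polygon_is_simple(v))
    stop("surface '", name, "': polygon is self-intersecting", call. = FALSE)
  stopifnot(is.numeric(areal_density), length(areal_density) == 1L,
            areal_density > 0)
  structure(list(name = name, vertices = v,
                 areal_density = as.numeric(areal_density)),
            class = "control_surface")
}

#' @export
print.control_surface <- function(x, ...) {
  cat(sprintf("<control_surface> %s: %d vertices, area %.3f cm^2, %.3f g/cm^2\n",
              x$name, nrow(x$vertices), polygon_area(x$vertices),
              x$areal_density))
  invisible(x)
}

#' Construct a fish model from control surfaces
#'
#' The morphological unit of the analysis: one head and one body polygon
#' (fins optional), the hinge point about which the head rotates, and the
#' centre of mass about which the whole model yaws. Head area is checked
#' against `head_area_target` (the study normalises every head to the same
#' projected area so that head MOI differences reflect shape alone).
#'
#' @param species_id Character scalar identifying the species/model.
#' @param surfaces List of [control_surface()] objects; exactly one `head` and
#'   one `body`, at most one of each fin.
#' @param hinge_point Numeric length-2, cm: the head's rotation axis seen in
#'   the lateral plane. Must lie on or inside the head--body union.
#' @param com_point Numeric length-2, cm: the model's centre of mass (the yaw
#'   axis of the mounted model). Computed from surface masses when `NULL`.
#' @param head_area_target Head projected area, cm^2 (default 30).
#' @param landmarks Optional 4 x 2 matrix of reference landmark positions
#'   (anterior head tip; posterior head tip at the hinge; anterior ventral
#'   body tip; posterior body tip). Derived from the polygons when `NULL`.
#' @param check_head_area If `TRUE` (default) require the head polygon area to
#'   match `head_area_target` within 0.1%.
#' @return A `fish_model` object.
#' @export
fish_model <- function(species_id, surfaces, hinge_point, com_point = NULL,
                       head_area_target = 30, landmarks = NULL,
                       check_head_area = TRUE) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (!is.list(surfaces) ||
      !all(vapply(surfaces, inherits, logical(1), "control_surface")))
    stop("surfaces must be a list of control_surface objects", call. = FALSE)
  nms <- vapply(surfaces, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate control-surface names: ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  if (sum(nms == "head") != 1L || sum(nms == "body") != 1L)
    stop("a fish_model needs exactly one head and one body surface",
         call. = FALSE)
  names(surfaces) <- nms
  stopifnot(is.numeric(hinge_point), length(hinge_point) == 2L,
            all(is.finite(hinge_point)))
  head_area <- polygon_area(surfaces[["head"]]$vertices)
  if (check_head_area &&
      abs(head_area - head_area_target) > 1e-3 * head_area_target)
    stop(sprintf(
      "head area %.4f cm^2 differs from target %.4f cm^2 by more than 0.1%%",
      head_area, head_area_target), call. = FALSE)
  if (is.null(com_point)) {
    com_point <- model_com(surfaces)
  }
  stopifnot(is.numeric(com_point), length(com_point) == 2L,
            all(is.finite(com_point)))
  if (!point_in_union(hinge_point, surfaces[c("head", "body")]))
    stop("hinge_point must lie on or inside the head-body union",
         call. = FALSE)
  if (is.null(landmarks)) landmarks <- derive_landmarks(surfaces, hinge_point)
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(landmarks) == 4L, ncol(landmarks) == 2L)
  structure(list(species_id = species_id, surfaces = surfaces,
                 hinge_point = as.numeric(hinge_point),
                 com_point = as.numeric(com_point),
                 head_area_target = head_area_target,
                 landmarks = landmarks),
            class = "fish_model")
}

# mass-weighted centroid over all surfaces
model_com <- function(surfaces) {
  ms <- vapply(surfaces, function(s) polygon_area(s$vertices) * s$areal_density,
               numeric(1))
  cs <- vapply(surfaces, function(s) polygon_centroid(s$vertices), numeric(2))
  as.numeric(cs %*% ms / sum(ms))
}

point_in_union <- function(p, surfaces, tol = 1e-6) {
  for (s in surfaces) {
    if (points_in_polygon(s$vertices, p[1L], p[2L])) return(TRUE)
    # boundary tolerance: nudge the point in four directions
    for (d in list(c(tol, 0), c(-tol, 0), c(0, tol), c(0, -tol))) {
      if (points_in_polygon(s$vertices, p[1L] + d[1L], p[2L] + d[2L]))
        return(TRUE)
    }
  }
  FALSE
}

# Landmark scheme used on the physical models, digitized in the VENTRAL view
# (the camera films the yaw plane from below): 1 anterior head tip, 2
# posterior head tip (hinge), 3 anterior ventral body tip, 4 posterior body
# tip. A laterally symmetric model puts all four on the midline (y = 0 in the
# yaw plane) at rest, so the resting head-body angle is zero; x positions come
# from the lateral silhouette.
derive_landmarks <- function(surfaces, hinge_point) {
  hv <- surfaces[["head"]]$vertices
  bv <- surfaces[["body"]]$vertices
  x_extent <- max(bv[, 1L]) - min(bv[, 1L])
  rbind(l1 = c(min(hv[, 1L]), 0),
        l2 = c(hinge_point[1L], 0),
        l3 = c(hinge_point[1L] + 0.05 * x_extent, 0),
        l4 = c(max(bv[, 1L]), 0))
}

#' @export
print.fish_model <- function(x, ...) {
  cat(sprintf("<fish_model> %s: %d surfaces (%s)\n", x$species_id,
              length(x$surfaces), paste(names(x$surfaces), collapse = ", ")))
  cat(sprintf("  hinge (%.2f, %.2f) cm; COM (%.2f, %.2f) cm; head area %.2f cm^2\n",
              x$hinge_point[1L], x$hinge_point[2L], x$com_point[1L],
              x$com_point[2L], polygon_area(x$surfaces$head$vertices)))
  invisible(x)
}

#' Write / read a fish model as a silhouette JSON document
#'
#' The document stores the species id, per-surface vertex arrays (cm) and
#' areal densities, hinge and COM coordinates, head area target and reference
#' landmarks.
#'
#' @param model A [fish_model()].
#' @param path File path.
#' @return `read_silhouette_json()` returns a `fish_model`;
#'   `write_silhouette_json()` returns `path` invisibly.
#' @export
write_silhouette_json <- function(model, path) {
  stopifnot(inherits(model, "fish_model"))
  doc <- list(
    species_id = model$species_id,
    head_area_target = model$head_area_target,
    hinge_point = model$hinge_point,
    com_point = model$com_point,
    landmarks = model$landmarks,
    surfaces = lapply(unname(model$surfaces), function(s)
      list(name = s$name, areal_density = s$areal_density,
           vertices = unname(s$vertices)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_silhouette_json
#' @export
read_silhouette_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  surfaces <- lapply(seq_len(nrow(doc$surfaces)), function(i) {
    row <- doc$surfaces[i, ]
    control_surface(row$name, row$vertices[[1L]], row$areal_density)
  })
  fish_model(doc$species_id, surfaces, doc$hinge_point, doc$com_point,
             head_area_target = doc$head_area_target,
             landmarks = doc$landmarks)
}

#' Read a binary mask image (PNG) with a resolution sidecar
#'
#' Accepts one PNG per control surface plus a JSON sidecar carrying at least
#' `resolution` (cm/pixel) and optionally `origin` (cm). Foreground is any
#' pixel with intensity > 0.5. Image rows are flipped so that mask row 1 is
#' the bottom of the image, matching [rasterize_polygon()].
#'
#' @param png_path Path to the PNG mask.
#' @param sidecar_path Path to the JSON sidecar; defaults to the PNG path with
#'   a `.json` extension.
#' @return A list with `mask`, `origin`, `resolution`.
#' @export
read_mask_png <- function(png_path,
                          sidecar_path = sub("\\.png$", ".json", png_path)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG masks requires the 'png' package", call. = FALSE)
  img <- png::readPNG(png_path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- img[rev(seq_len(nrow(img))), , drop = FALSE] > 0.5
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  stopifnot(!is.null(side$resolution), side$resolution > 0)
  origin <- if (!is.null(side$origin)) as.numeric(side$origin) else c(0, 0)
  list(mask = mask, origin = origin, resolution = side$resolution)
}
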