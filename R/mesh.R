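#' Triangulated cortical surface mesh
#'
#' Container for a shared surface mesh: vertex coordinates (mm), triangles,
#' per-vertex neighbor lists, per-vertex areas (one third of the incident
#' triangle areas, mm^2) and a boolean region-of-interest mask marking the
#' vertices to be parcellated.
#'
#' @param coords numeric matrix, vertices x 3, coordinates in mm.
#' @param triangles integer matrix, triangles x 3, 1-based vertex indices.
#' @param roi_mask logical vector marking ROI vertices; defaults to all
#'   vertices.
#' @return An object of class `surface_mesh` with elements `coords`,
#'   `triangles`, `neighbors`, `vertex_area`, `roi_mask`.
#' @export
surface_mesh <- function(coords, triangles, roi_mask = NULL) {
  coords <- as.matrix(coords)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(coords) <- NULL
  dimnames(triangles) <- NULL
  nv <- nrow(coords)
  if (ncol(coords) != 3L || ncol(triangles) != 3L) {
    fc_abort("coords and triangles must have 3 columns", "fcparc_dimension_error")
  }
  if (any(triangles < 1L) || any(triangles > nv)) {
    fc_abort("triangle indices must lie in 1..n_vertices", "fcparc_validation_error")
  }
  if (is.null(roi_mask)) roi_mask <- rep(TRUE, nv)
  if (length(roi_mask) != nv) {
    fc_abort("roi_mask length must equal vertex count", "fcparc_dimension_error")
  }

  tri_area <- triangle_areas(coords, triangles)
  vertex_area <- numeric(nv)
  for (j in 1:3) {
    va <- rowsum(tri_area / 3, triangles[, j])
    idx <- as.integer(rownames(va))
    vertex_area[idx] <- vertex_area[idx] + va[, 1]
  }
  if (any(vertex_area <= 0)) {
    fc_abort("every vertex must belong to at least one triangle", "fcparc_validation_error")
  }

  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  nb <- split(to, factor(from, levels = seq_len(nv)))
  neighbors <- lapply(nb, function(v) sort(unique(v)))

  structure(
    list(
      coords = coords,
      triangles = triangles,
      neighbors = neighbors,
      vertex_area = vertex_area,
      roi_mask = as.logical(roi_mask)
    ),
    class = "surface_mesh"
  )
}

triangle_areas <- function(coords, triangles) {
  a <- coords[triangles[, 2], , drop = FALSE] - coords[triangles[, 1], , drop = FALSE]
  b <- coords[triangles[, 3], , drop = FALSE] - coords[triangles[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d triangles, %d ROI vertices, total area %.1f mm^2\n",
    nrow(x$coords), nrow(x$triangles), sum(x$roi_mask), sum(x$vertex_area)
  ))
  invisible(x)
}

# unit icosahedron
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(coords = v, triangles = f)
}

subdivide_once <- function(coords, triangles) {
  nv <- nrow(coords)
  e1 <- cbind(triangles[, 1], triangles[, 2])
  e2 <- cbind(triangles[, 2], triangles[, 3])
  e3 <- cbind(triangles[, 3], triangles[, 1])
  all_e <- rbind(e1, e2, e3)
  lo <- pmin(all_e[, 1], all_e[, 2])
  hi <- pmax(all_e[, 1], all_e[, 2])
  key <- lo * (nv + 1) + hi
  uk <- !duplicated(key)
  mid_of <- match(key, key[uk]) + nv
  mids <- (coords[lo[uk], , drop = FALSE] + coords[hi[uk], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nt <- nrow(triangles)
  m12 <- mid_of[seq_len(nt)]
  m23 <- mid_of[nt + seq_len(nt)]
  m31 <- mid_of[2 * nt + seq_len(nt)]
  new_tri <- rbind(
    cbind(triangles[, 1], m12, m31),
    cbind(triangles[, 2], m23, m12),
    cbind(triangles[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(coords = rbind(coords, mids), triangles = new_tri)
}

#' Build an icosphere surface mesh
#'
#' Constructs a geodesic sphere by repeated subdivision of an icosahedron,
#' projected to a sphere of the given radius. After n subdivisions the mesh
#' has 10 * 4^n + 2 vertices; every non-original vertex has exactly six
#' neighbors, mimicking the regular neighborhood structure of a standard
#' average cortical surface. A contiguous polar cap of roughly
#' `roi_fraction` of the vertices is marked as the parcellation region of
#' interest.
#'
#' @param subdivisions number of subdivision rounds (0-7).
#' @param radius sphere radius in mm (default 100, giving cortex-like vertex
#'   areas at subdivision levels 3-6).
#' @param roi_fraction fraction of vertices in the ROI cap (default 0.25).
#' @return A [surface_mesh()].
#' @examples
#' mesh <- build_mesh(2)
#' sum(mesh$roi_mask)
#' @export
build_mesh <- function(subdivisions, radius = 100, roi_fraction = 0.25) {
  if (subdivisions < 0) {
    fc_abort("subdivisions must be >= 0", "fcparc_parameter_error")
  }
  if (subdivisions > 7) {
    fc_abort(
      "subdivisions > 7 would build an excessively large mesh",
      "fcparc_resource_error"
    )
  }
  ico <- icosahedron()
  for (i in seq_len(subdivisions)) {
    ico <- subdivide_once(ico$coords, ico$triangles)
  }
  coords <- ico$coords * radius

  # contiguous cap around the vertex closest to the +z pole
  pole <- which.max(ico$coords[, 3])
  ang <- acos(pmin(1, pmax(-1, ico$coords %*% ico$coords[pole, ])))
  n_roi <- max(2L, round(roi_fraction * nrow(coords)))
  roi <- rank(ang, ties.method = "first") <= n_roi

  surface_mesh(coords, ico$triangles, roi_mask = roi)
}
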