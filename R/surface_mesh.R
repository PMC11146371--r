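#' Triangulated vascular surface mesh
#'
#' A `surface_mesh` holds a watertight triangulation of the vessel lumen
#' boundary with per-triangle region tags and, optionally, the neck plane
#' separating the aneurysm dome from the parent vessel. Coordinates are in
#' millimetres throughout the package; the flow solver converts to SI
#' internally.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices,
#'   consistently oriented with outward normals.
#' @param region_tags character vector of length m; conventional values are
#'   `"wall"`, `"dome"`, `"inlet"` and `"outlet_1"`, `"outlet_2"`, ...
#' @param neck_plane optional `list(point = , normal = )` in mm / unit vector,
#'   with the normal pointing into the dome. Imported meshes may omit it, in
#'   which case dome-relative quantities are unavailable.
#' @param validate check watertightness and triangle validity (default TRUE).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, region_tags,
                         neck_plane = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            length(region_tags) == nrow(triangles))
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         region_tags = as.character(region_tags), neck_plane = neck_plane),
    class = "surface_mesh")
  if (validate) {
    if (any(triangle_areas(mesh) <= 0))
      stop("surface_mesh: degenerate (zero-area) triangles present")
    if (!mesh_is_watertight(mesh))
      stop("surface_mesh: mesh is not watertight / consistently oriented")
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  tab <- table(x$region_tags)
  ar <- vapply(names(tab), function(tag)
    sum(triangle_areas(x)[x$region_tags == tag]), numeric(1))
  cat("  regions:", paste(sprintf("%s (%d tris, %.1f mm^2)",
                                  names(tab), as.integer(tab), ar),
                          collapse = ", "), "\n")
  if (!is.null(x$neck_plane)) cat("  neck plane recorded\n")
  invisible(x)
}

#' Watertightness / orientation check
#'
#' A closed, consistently oriented triangulation has every directed edge
#' exactly once, i.e. every undirected edge shared by exactly two triangles
#' in opposite directions.
#'
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  from <- as.numeric(c(tr[, 1], tr[, 2], tr[, 3]))
  to <- as.numeric(c(tr[, 2], tr[, 3], tr[, 1]))
  n <- nrow(mesh$vertices)
  key_dir <- (from - 1) * n + to
  if (anyDuplicated(key_dir) > 0) return(FALSE)
  key_und <- pmin(from, to) * n + pmax(from, to)
  all(table(key_und) == 2L)
}

#' Triangle areas of a surface mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector, one area per triangle.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Outward unit normals per triangle
#' @param mesh a `surface_mesh`.
#' @return numeric matrix (m x 3).
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm / sqrt(rowSums(nrm^2))
}

#' Triangle centroids (mm)
#' @param mesh a `surface_mesh`.
#' @return numeric matrix (m x 3).
#' @export
triangle_centroids <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

#' Volume enclosed by a watertight surface (mm^3)
#'
#' Divergence-theorem volume; positive for outward-oriented meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric scalar.
#' @export
enclosed_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Area covered by each region tag
#' @param mesh a `surface_mesh`.
#' @return named numeric vector of areas (mm^2).
#' @export
region_areas <- function(mesh) {
  ar <- triangle_areas(mesh)
  vapply(split(ar, mesh$region_tags), sum, numeric(1))
}

# vertex ids used by triangles with the given tags
region_vertex_ids <- function(mesh, tags) {
  sort(unique(as.vector(mesh$triangles[mesh$region_tags %in% tags, ])))
}
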