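#' Smooth a surface mesh
#'
#' Two classic umbrella-weight filters: `"lowpass"` is Taubin lambda|mu
#' smoothing (alternating positive and negative Laplacian steps), which
#' suppresses high-frequency noise while bounding volume shrinkage;
#' `"laplace"` is plain Laplacian relaxation, which smooths faster but
#' shrinks the surface monotonically. Connectivity and region tags are
#' unchanged; only vertex positions move.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param method `"lowpass"` (Taubin) or `"laplace"`.
#' @param iterations number of filter passes (0 returns the input).
#' @param lambda,mu Taubin step sizes (lowpass only).
#' @param relaxation Laplacian step size (laplace only).
#' @return the smoothed `surface_mesh`.
#' @export
smooth_surface <- function(mesh, method = c("lowpass", "laplace"),
                           iterations = 10, lambda = 0.5, mu = -0.53,
                           relaxation = 0.5) {
  method <- match.arg(method)
  if (!mesh_is_watertight(mesh))
    stop("smooth_surface requires a watertight input mesh")
  if (iterations == 0) return(mesh)
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3], tr[, 2], tr[, 3], tr[, 1])
  to <- c(tr[, 2], tr[, 3], tr[, 1], tr[, 1], tr[, 2], tr[, 3])
  key <- paste(from, to)
  keep <- !duplicated(key)
  from <- from[keep]
  to <- to[keep]
  n <- nrow(mesh$vertices)
  deg <- tabulate(from, n)
  umbrella <- function(v) {
    s <- rowsum(v[to, , drop = FALSE], from, reorder = TRUE)
    s / deg - v
  }
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda_step(method, 1, lambda, relaxation) * umbrella(v)
    if (method == "lowpass") v <- v + mu * umbrella(v)
  }
  out <- mesh
  out$vertices <- v
  out
}

lambda_step <- function(method, pass, lambda, relaxation) {
  if (method == "lowpass") lambda else relaxation
}

#' Extend vessel openings to satisfy the six-diameter rule
#'
#' Each tagged opening (inlet / outlet cap) is extruded along its outward
#' cap normal until the straight run between the opening and the aneurysm
#' dome is at least `min_length_factor` times the opening diameter, so that
#' fully developed flow can establish before reaching the aneurysm.
#' The terminal cross-section is the translated original cap: exactly the
#' same shape, perpendicular to the extension axis. Meshes without a dome
#' region are left unchanged (there is nothing to be remote from).
#'
#' @param mesh a watertight tagged `surface_mesh`.
#' @param min_length_factor required run length in opening diameters
#'   (default 6).
#' @return the extended `surface_mesh`.
#' @export
extend_openings <- function(mesh, min_length_factor = 6) {
  caps <- unique(grep("^(inlet|outlet)", mesh$region_tags, value = TRUE))
  if (length(caps) == 0) stop("no tagged inlet/outlet caps present")
  dome_v <- region_vertex_ids(mesh, "dome")
  if (length(dome_v) == 0) return(mesh)
  for (cap in caps) mesh <- extend_one_opening(mesh, cap, min_length_factor)
  mesh
}

extend_one_opening <- function(mesh, cap, factor) {
  sel <- which(mesh$region_tags == cap)
  ar <- triangle_areas(mesh)[sel]
  nrm <- triangle_normals(mesh)[sel, , drop = FALSE]
  cent <- triangle_centroids(mesh)[sel, , drop = FALSE]
  axis <- colSums(nrm * ar)
  axis <- axis / sqrt(sum(axis^2))
  center <- colSums(cent * ar) / sum(ar)
  area <- sum(ar)
  diameter <- 2 * sqrt(area / pi)
  cap_v <- region_vertex_ids(mesh, cap)
  offplane <- abs((mesh$vertices[cap_v, , drop = FALSE] -
                     matrix(center, length(cap_v), 3, byrow = TRUE)) %*% axis)
  if (max(offplane) > 0.05 * diameter)
    stop("opening '", cap, "' is not approximately planar (max deviation ",
         signif(max(offplane), 3), " mm)")
  dome_v <- region_vertex_ids(mesh, "dome")
  # straight run from the cap plane to the nearest dome vertex, measured
  # along the inward axis
  run <- min((mesh$vertices[dome_v, , drop = FALSE] -
                matrix(center, length(dome_v), 3, byrow = TRUE)) %*% (-axis))
  needed <- factor * diameter - run
  if (needed <= 1e-9) return(mesh)

  # ordered boundary loop of the cap, in cap-facet winding direction
  tr <- mesh$triangles
  from <- as.numeric(c(tr[, 1], tr[, 2], tr[, 3]))
  to <- as.numeric(c(tr[, 2], tr[, 3], tr[, 1]))
  fac <- rep(seq_len(nrow(tr)), 3)
  in_cap <- fac %in% sel
  n <- nrow(mesh$vertices)
  dirkey <- (from - 1) * n + to
  revkey <- (to - 1) * n + from
  rev_in_cap <- in_cap[match(revkey, dirkey)]
  bsel <- in_cap & !rev_in_cap
  loop_from <- from[bsel]
  loop_to <- to[bsel]
  nxt <- stats::setNames(loop_to, loop_from)
  loop <- integer(length(loop_from))
  loop[1] <- loop_from[1]
  for (i in seq_len(length(loop) - 1)) loop[i + 1] <- nxt[as.character(loop[i])]
  if (anyDuplicated(loop) || nxt[as.character(loop[length(loop)])] != loop[1])
    stop("opening '", cap, "' boundary is not a single closed loop")

  interior <- setdiff(cap_v, loop)
  other_f <- setdiff(seq_len(nrow(tr)), sel)
  if (length(interior) &&
      any(interior %in% as.vector(tr[other_f, , drop = FALSE])))
    stop("opening '", cap, "' interior vertices are shared with other regions")

  edge_len <- mean(sqrt(rowSums((mesh$vertices[loop_to, , drop = FALSE] -
                                   mesh$vertices[loop_from, , drop = FALSE])^2)))
  m <- max(1L, ceiling(needed / edge_len))
  delta <- needed / m
  nl <- length(loop)
  v <- mesh$vertices
  newtris <- matrix(0L, 0, 3)
  prev <- loop
  for (l in seq_len(m)) {
    ids <- nrow(v) + seq_len(nl)
    v <- rbind(v, mesh$vertices[loop, , drop = FALSE] +
                 matrix(axis * (l * delta), nl, 3, byrow = TRUE))
    a <- prev
    b <- prev[c(2:nl, 1)]
    a1 <- ids
    b1 <- ids[c(2:nl, 1)]
    newtris <- rbind(newtris, cbind(a, b, b1), cbind(a, b1, a1))
    prev <- ids
  }
  # translate interior cap vertices, remap the rim to the last new ring
  if (length(interior))
    v[interior, ] <- v[interior, , drop = FALSE] +
      matrix(axis * needed, length(interior), 3, byrow = TRUE)
  remap <- seq_len(nrow(v))
  remap[loop] <- prev
  tr[sel, ] <- matrix(remap[tr[sel, ]], ncol = 3)
  out <- surface_mesh(v, rbind(tr, newtris),
                      c(mesh$region_tags, rep("wall", nrow(newtris))),
                      neck_plane = mesh$neck_plane)
  attr(out, "generator") <- NULL  # extended geometry no longer matches it
  out
}

#' Aneurysm morphometry
#'
#' Computes the standard morphological descriptors over the dome-tagged
#' region: size (maximum pairwise distance within the dome), dome surface
#' area and enclosed volume (dome surface closed by a fan over the neck
#' loop), and -- when the neck plane is recorded -- the neck diameter
#' (maximum chord of the dome boundary loop projected into the neck plane),
#' the height (maximum perpendicular distance of the dome from the neck
#' plane) and the aspect ratio height / neck diameter. Without a neck plane
#' only size, volume and area are reported, mirroring imported meshes whose
#' neck cannot be defined.
#'
#' @param mesh a `surface_mesh` with a `dome` region.
#' @return a `morphometry_report` (named list).
#' @export
compute_morphometry <- function(mesh) {
  dome_f <- which(mesh$region_tags == "dome")
  if (length(dome_f) == 0) stop("mesh has no dome-tagged facets")
  if (length(dome_f) < 4) stop("degenerate dome region (fewer than 4 facets)")
  dome_v <- region_vertex_ids(mesh, "dome")
  size <- max_pairwise_distance_cpp(mesh$vertices[dome_v, , drop = FALSE])
  area <- sum(triangle_areas(mesh)[dome_f])

  # dome boundary loop (edges shared with non-dome facets)
  tr <- mesh$triangles
  from <- as.numeric(c(tr[, 1], tr[, 2], tr[, 3]))
  to <- as.numeric(c(tr[, 2], tr[, 3], tr[, 1]))
  fac <- rep(seq_len(nrow(tr)), 3)
  in_dome <- fac %in% dome_f
  n <- nrow(mesh$vertices)
  dirkey <- (from - 1) * n + to
  revkey <- (to - 1) * n + from
  rev_in_dome <- in_dome[match(revkey, dirkey)]
  bsel <- which(in_dome & !rev_in_dome)
  la <- from[bsel]
  lb <- to[bsel]
  loop_v <- unique(c(la, lb))
  c0 <- colMeans(mesh$vertices[loop_v, , drop = FALSE])

  # enclosed dome volume: dome facets plus the closing fan (b, a, c0)
  v <- mesh$vertices
  vol6 <- function(p1, p2, p3)
    p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  volume <- sum(vol6(v[tr[dome_f, 1], , drop = FALSE],
                     v[tr[dome_f, 2], , drop = FALSE],
                     v[tr[dome_f, 3], , drop = FALSE])) / 6 +
    sum(vol6(v[lb, , drop = FALSE], v[la, , drop = FALSE],
             matrix(c0, length(la), 3, byrow = TRUE))) / 6

  out <- list(size = size, volume = volume, surface_area = area,
              neck_diameter = NA_real_, height = NA_real_,
              aspect_ratio = NA_real_)
  np <- mesh$neck_plane
  if (!is.null(np)) {
    nrm <- np$normal / sqrt(sum(np$normal^2))
    rel <- mesh$vertices[dome_v, , drop = FALSE] -
      matrix(np$point, length(dome_v), 3, byrow = TRUE)
    out$height <- max(rel %*% nrm)
    # neck section: intersection polyline of the neck plane with the
    # dome-side surface; fall back to the projected dome boundary loop when
    # the loop already lies in the plane (no crossing triangles)
    sd_all <- (mesh$vertices - matrix(np$point, n, 3, byrow = TRUE)) %*% nrm
    tv <- matrix(sd_all[tr[dome_f, ]], ncol = 3)
    cross_tri <- dome_f[apply(tv, 1, min) < 0 & apply(tv, 1, max) > 0]
    pts <- matrix(0, 0, 3)
    for (f in cross_tri) {
      vid <- tr[f, ]
      for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
        s1 <- sd_all[vid[e[1]]]
        s2 <- sd_all[vid[e[2]]]
        if ((s1 < 0) != (s2 < 0)) {
          t <- s1 / (s1 - s2)
          pts <- rbind(pts, (1 - t) * v[vid[e[1]], ] + t * v[vid[e[2]], ])
        }
      }
    }
    if (nrow(pts) >= 6) {
      out$neck_diameter <- max_pairwise_distance_cpp(pts)
    } else {
      rel_loop <- mesh$vertices[loop_v, , drop = FALSE] -
        matrix(np$point, length(loop_v), 3, byrow = TRUE)
      proj <- rel_loop - (rel_loop %*% nrm) %*% t(nrm)
      out$neck_diameter <- max_pairwise_distance_cpp(proj)
    }
    out$aspect_ratio <- out$height / out$neck_diameter
  }
  structure(out, class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("aneurysm morphometry:\n")
  cat(sprintf("  size          %8.2f mm\n", x$size))
  cat(sprintf("  volume        %8.1f mm^3\n", x$volume))
  cat(sprintf("  surface area  %8.1f mm^2\n", x$surface_area))
  if (!is.na(x$neck_diameter)) {
    cat(sprintf("  neck diameter %8.2f mm\n", x$neck_diameter))
    cat(sprintf("  height        %8.2f mm\n", x$height))
    cat(sprintf("  aspect ratio  %8.2f\n", x$aspect_ratio))
  } else {
    cat("  neck plane not defined: neck diameter / height / aspect ratio absent\n")
  }
  invisible(x)
}
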