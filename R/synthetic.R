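#' Configuration for the idealized aneurysm generator
#'
#' The defaults emulate the study population morphology: a parent artery of
#' radius about 2 mm carrying a saccular dome of about 9 mm maximal size with
#' a neck of about 5 mm diameter and aspect ratio near 1.5. The dome is a
#' sphere intersecting the parent tube; the neck plane is placed where the
#' sphere cross-section equals the requested neck radius.
#'
#' @param parent_radius parent artery radius (mm).
#' @param parent_length parent artery length (mm); must be at least 12 x
#'   `parent_radius` so both openings satisfy the six-diameter rule.
#' @param dome_radius dome sphere radius (mm).
#' @param neck_radius neck radius (mm), must be smaller than `dome_radius`.
#' @param dome_offset height of the dome sphere centre above the vessel axis
#'   (mm); `NULL` places the neck plane slightly inside the parent wall.
#' @param bleb optional secondary bleb, `list(radius = , direction = )` with
#'   `direction` a unit vector from the dome centre.
#' @param bifurcation logical; `FALSE` (default) builds a sidewall aneurysm on
#'   a straight parent vessel, `TRUE` a terminal aneurysm at a Y bifurcation.
#' @param mesh_edge_length target surface edge length (mm).
#' @param seed integer; controls only the bleb placement jitter.
#' @return a `aneurysm_config` list.
#' @export
aneurysm_config <- function(parent_radius = 2.0, parent_length = 25.0,
                            dome_radius = 4.5, neck_radius = 2.6,
                            dome_offset = NULL, bleb = NULL,
                            bifurcation = FALSE, mesh_edge_length = 0.35,
                            seed = 1L) {
  if (parent_radius <= 0 || mesh_edge_length <= 0)
    stop("parent_radius and mesh_edge_length must be positive")
  if (neck_radius >= dome_radius)
    stop("invalid configuration: neck_radius must be smaller than dome_radius")
  if (parent_length < 12 * parent_radius)
    stop("parent_length must be at least 12 x parent_radius (six-diameter rule)")
  if (is.null(dome_offset))
    dome_offset <- parent_radius + sqrt(dome_radius^2 - neck_radius^2) -
      0.1 * neck_radius
  if (!is.null(bleb)) {
    stopifnot(is.list(bleb), bleb$radius > 0, length(bleb$direction) == 3)
    bleb$direction <- bleb$direction / sqrt(sum(bleb$direction^2))
  }
  structure(list(parent_radius = parent_radius, parent_length = parent_length,
                 dome_radius = dome_radius, neck_radius = neck_radius,
                 dome_offset = dome_offset, bleb = bleb,
                 bifurcation = bifurcation,
                 mesh_edge_length = mesh_edge_length, seed = as.integer(seed)),
            class = "aneurysm_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# primitive table rows for the implicit union (see lattice_mesh.cpp)
prim_sphere <- function(c, r) c(1, c, r, 0, 0, 0, 0)
prim_cyl_inf <- function(a, d, r) c(2, a, d, r, 0)
prim_cyl_cap <- function(a, d, r, hl) c(3, a, d, r, hl)

# geometry description shared by the builder and tetrahedralize()
aneurysm_primitives <- function(config) {
  rp <- config$parent_radius
  L <- config$parent_length
  rd <- config$dome_radius
  rn <- config$neck_radius
  zc <- config$dome_offset
  zn <- zc - sqrt(rd^2 - rn^2)
  if (config$bifurcation) {
    # parent along +x up to the junction; two daughters in the xy-plane;
    # the dome sits on the flow-divider axis beyond the junction
    xj <- 0.6 * L
    rdau <- 0.8 * rp
    ldau <- max(8 * rdau, L - xj)
    ang <- 40 * pi / 180
    d1 <- c(cos(ang), sin(ang), 0)
    d2 <- c(cos(ang), -sin(ang), 0)
    a1 <- c(xj, 0, 0) + d1 * ldau / 2
    a2 <- c(xj, 0, 0) + d2 * ldau / 2
    cdome <- c(xj + zc, 0, 0)
    prims <- rbind(prim_cyl_cap(c(xj / 2 - rp, 0, 0), c(1, 0, 0), rp,
                                xj / 2 + rp),
                   prim_cyl_cap(a1, d1, rdau, ldau / 2),
                   prim_cyl_cap(a2, d2, rdau, ldau / 2),
                   prim_sphere(cdome, rd))
    dome_rows <- 4L
    if (!is.null(config$bleb)) {
      bl <- bleb_sphere(config, cdome)
      prims <- rbind(prims, bl)
      dome_rows <- c(4L, 5L)
    }
    ext <- max(a1[1] + d1[1] * ldau / 2, cdome[1] + rd) + 1
    wid <- max(abs(a1[2]) + ldau / 2 + rdau, rd) + 1
    list(prims = prims, dome_rows = dome_rows,
         lower = c(0, -wid, -max(rp, rd) - 1),
         upper = c(ext, wid, max(rp, rd) + 1),
         neck_plane = list(point = c(xj + zc - sqrt(rd^2 - rn^2), 0, 0),
                           normal = c(1, 0, 0)),
         outlets = list(list(point = a1 + d1 * ldau / 2, normal = d1, radius = rdau),
                        list(point = a2 + d2 * ldau / 2, normal = d2, radius = rdau)),
         axis_planes = c(0, NA))
  } else {
    cdome <- c(L / 2, 0, zc)
    if (zn >= rp)
      stop("invalid configuration: dome does not reach the parent vessel ",
           "(neck plane at z = ", round(zn, 3), " mm, wall at ", rp, " mm)")
    if (zc - rd < -rp)
      stop("invalid configuration: dome swallows the parent tube ",
           "(sphere reaches z = ", round(zc - rd, 3), " mm)")
    reach <- rd + if (is.null(config$bleb)) 0 else 2 * config$bleb$radius
    if (L / 2 - reach < 2 * config$mesh_edge_length ||
        L / 2 + reach > L - 2 * config$mesh_edge_length)
      stop("invalid configuration: dome overlaps the inlet/outlet openings")
    prims <- rbind(prim_cyl_inf(c(0, 0, 0), c(1, 0, 0), rp),
                   prim_sphere(cdome, rd))
    dome_rows <- 2L
    if (!is.null(config$bleb)) {
      prims <- rbind(prims, bleb_sphere(config, cdome))
      dome_rows <- c(2L, 3L)
    }
    top <- max(zc + rd, if (is.null(config$bleb)) -Inf else
      (cdome + config$bleb$direction * (rd + 1.45 * config$bleb$radius))[3]) + 1
    wid <- max(rp, rd) + 1
    list(prims = prims, dome_rows = dome_rows,
         lower = c(0, -wid, -rp - 1), upper = c(L, wid, max(top, rp + 1)),
         neck_plane = list(point = c(L / 2, 0, zn), normal = c(0, 0, 1)),
         outlets = list(list(point = c(L, 0, 0), normal = c(1, 0, 0), radius = rp)),
         axis_planes = c(0, L))
  }
}

bleb_sphere <- function(config, cdome) {
  dir <- config$bleb$direction
  dir <- with_seed(config$seed, {
    j <- rnorm(3, 0, 0.05)
    d <- dir + j - dir * sum(dir * j)
    d / sqrt(sum(d^2))
  })
  prim_sphere(cdome + dir * (config$dome_radius + 0.45 * config$bleb$radius),
              config$bleb$radius)
}

# is every boundary edge shared by exactly two faces in opposite directions?
manifold_boundary <- function(nverts, faces) {
  from <- as.numeric(c(faces[, 1], faces[, 2], faces[, 3]))
  to <- as.numeric(c(faces[, 2], faces[, 3], faces[, 1]))
  if (anyDuplicated((from - 1) * nverts + to) > 0) return(FALSE)
  ku <- pmin(from, to) * nverts + pmax(from, to)
  all(tabulate(match(ku, unique(ku))) == 2L)
}

# clip the lattice against the implicit geometry; a pinched (non-manifold)
# boundary is a measure-zero lattice-alignment artifact, so retry with the
# transverse box bounds nudged by irrational fractions of the spacing
lattice_clip <- function(geom, spacing) {
  for (off in c(0, 0.3183, 0.5772, 0.7071)) {
    lower <- geom$lower - c(0, off, off) * spacing
    res <- lattice_mesh_primitives_cpp(geom$prims, lower, geom$upper,
                                       rep(spacing, 3), 0.3)
    bd <- boundary_faces_cpp(res$vertices, res$tets)
    if (manifold_boundary(nrow(res$vertices), bd$faces))
      return(list(res = res, bd = bd))
  }
  stop("lattice clipping produced a non-manifold boundary at every lattice offset")
}

# tag boundary facets of a lattice-meshed aneurysm
tag_aneurysm_boundary <- function(cent, geom, spacing) {
  tags <- rep("wall", nrow(cent))
  np <- geom$neck_plane
  above <- (cent %*% np$normal)[, 1] - sum(np$point * np$normal) > 0
  pd <- abs(prim_phi_cpp(geom$prims[geom$dome_rows, , drop = FALSE], cent))
  pv <- abs(prim_phi_cpp(geom$prims[-geom$dome_rows, , drop = FALSE], cent))
  tags[above & pd < pv] <- "dome"
  if (!is.na(geom$axis_planes[1]))
    tags[abs(cent[, 1] - geom$axis_planes[1]) < 1e-8] <- "inlet"
  if (!is.na(geom$axis_planes[2]))
    tags[abs(cent[, 1] - geom$axis_planes[2]) < 1e-8] <- "outlet_1"
  for (i in seq_along(geom$outlets)) {
    o <- geom$outlets[[i]]
    d <- abs((cent - matrix(o$point, nrow(cent), 3, byrow = TRUE)) %*% o$normal)[, 1]
    r2 <- rowSums((cent - matrix(o$point, nrow(cent), 3, byrow = TRUE))^2) - d^2
    sel <- d < 0.75 * spacing & r2 < (1.1 * o$radius)^2
    if (is.na(geom$axis_planes[2]) || i > 1)
      tags[sel] <- paste0("outlet_", i)
  }
  tags
}

#' Build an idealized saccular aneurysm surface
#'
#' The lumen is the union of a parent tube and a spherical dome (plus an
#' optional bleb), meshed by clipping a Freudenthal tetrahedral lattice
#' against the implicit surface with isosurface stuffing; the boundary of
#' that conforming volume mesh is returned, so the surface is watertight and
#' outward-oriented by construction. The inlet (and, for the sidewall
#' layout, the outlet) caps coincide with lattice planes and are exactly
#' planar circles perpendicular to the vessel axis.
#'
#' @param config an [aneurysm_config()].
#' @return a `surface_mesh` with tags `wall`, `dome`, `inlet`, `outlet_*`,
#'   a recorded neck plane and a generator attribute used by
#'   [tetrahedralize()] to remesh the same implicit geometry at other
#'   resolutions.
#' @export
build_idealized_aneurysm <- function(config) {
  stopifnot(inherits(config, "aneurysm_config"))
  geom <- aneurysm_primitives(config)
  spacing <- config$mesh_edge_length / 1.1
  clip <- lattice_clip(geom, spacing)
  res <- clip$res
  bd <- clip$bd
  used <- sort(unique(as.vector(bd$faces)))
  verts <- res$vertices[used, , drop = FALSE]
  tris <- matrix(match(as.vector(bd$faces), used), ncol = 3)
  cent <- (verts[tris[, 1], ] + verts[tris[, 2], ] + verts[tris[, 3], ]) / 3
  tags <- tag_aneurysm_boundary(cent, geom, spacing)
  mesh <- surface_mesh(verts, tris, tags, neck_plane = geom$neck_plane)
  attr(mesh, "generator") <- list(kind = "aneurysm", config = config,
                                  geom = geom)
  mesh
}

# ---- structured straight tube ----------------------------------------------

# spiderweb triangulation of a disc of radius R, edge target ds;
# returns 2d points (first column radial position along rings), triangle list
# (CCW for +x normal when mapped to (y,z)) and the outer ring ids
disc_triangulation <- function(R, ds) {
  nr <- max(2, round(R / ds))
  n1 <- max(6, round(2 * pi * (R / nr) / ds))
  pts <- matrix(0, 1, 2)
  ring_ids <- list()
  for (j in seq_len(nr)) {
    n <- n1 * j
    ang <- 2 * pi * (seq_len(n) - 1) / n
    ring_ids[[j]] <- nrow(pts) + seq_len(n)
    pts <- rbind(pts, cbind(R * j / nr * cos(ang), R * j / nr * sin(ang)))
  }
  tris <- matrix(0L, 0, 3)
  inner <- ring_ids[[1]]
  k <- length(inner)
  tris <- rbind(tris, cbind(inner, inner[c(2:k, 1)], 1L))
  for (j in seq_len(nr - 1)) {
    tris <- rbind(tris, bridge_rings(ring_ids[[j]], ring_ids[[j + 1]]))
  }
  list(points = pts, triangles = tris, outer = ring_ids[[nr]])
}

# triangulate the annulus between two uniform concentric rings (ids ordered
# by increasing angle); CCW orientation
bridge_rings <- function(inner, outer) {
  ni <- length(inner)
  no <- length(outer)
  ain <- 2 * pi * (seq_len(ni) - 1) / ni
  aout <- 2 * pi * (seq_len(no) - 1) / no
  tris <- matrix(0L, ni + no, 3)
  i <- 1L
  o <- 1L
  row <- 1L
  while (i <= ni || o <= no) {
    next_in <- if (i < ni) ain[i + 1] else if (i == ni) 2 * pi else Inf
    next_out <- if (o < no) aout[o + 1] else if (o == no) 2 * pi else Inf
    cin <- inner[(i - 1L) %% ni + 1L]
    cout <- outer[(o - 1L) %% no + 1L]
    if (next_out <= next_in && o <= no) {
      tris[row, ] <- c(cout, outer[o %% no + 1L], cin)
      o <- o + 1L
    } else {
      tris[row, ] <- c(cout, inner[i %% ni + 1L], cin)
      i <- i + 1L
    }
    row <- row + 1L
  }
  tris
}

# split a prism (bottom 1:3, top 4:6, vertical edges i -> i+3) into three
# tets with quad diagonals through each quad's smallest global vertex id
# (Dompierre et al.), which keeps neighbouring prisms conforming
prism_split <- function(p) {
  mi <- which.min(p)
  if (mi > 3) p <- p[c(4:6, 1:3)]
  r <- (which.min(p[1:3]) - 1L)
  idx <- c((0:2 + r) %% 3 + 1L, (0:2 + r) %% 3 + 4L)
  w <- p[idx]
  if (min(w[2], w[6]) < min(w[3], w[5]))
    rbind(w[c(1, 2, 3, 6)], w[c(1, 2, 6, 5)], w[c(1, 5, 6, 4)])
  else
    rbind(w[c(1, 2, 3, 5)], w[c(1, 5, 3, 6)], w[c(1, 5, 6, 4)])
}

#' Signed tetrahedron volumes (mm^3)
#' @param V vertex matrix (n x 3).
#' @param T tetrahedra (m x 4, 1-based).
#' @return numeric vector of signed volumes (positive for well-oriented tets).
#' @export
tet_volumes <- function(V, T) {
  a <- V[T[, 2], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  b <- V[T[, 3], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  d <- V[T[, 4], , drop = FALSE] - V[T[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

orient_tets <- function(V, T) {
  vol <- tet_volumes(V, T)
  neg <- vol < 0
  if (any(neg)) T[neg, 3:4] <- T[neg, 4:3]
  T
}

#' Structured tetrahedral mesh of a straight circular tube
#'
#' Cross-sections are meshed by a spiderweb disc triangulation and extruded
#' along the x axis into prisms split into tetrahedra, so cross-sections are
#' exactly circular and the end caps exactly planar. The axial spacing may
#' differ from the in-plane edge length; axially invariant flows (Poiseuille
#' verification) tolerate coarse axial resolution.
#'
#' @param radius tube radius (mm).
#' @param length tube length (mm), along +x from 0.
#' @param edge_length in-plane target edge (mm).
#' @param axial_edge_length axial spacing (mm), default `edge_length`.
#' @return a `volume_mesh` with tagged boundary (`inlet`, `outlet_1`, `wall`).
#' @export
tube_volume_mesh <- function(radius, length, edge_length,
                             axial_edge_length = edge_length) {
  stopifnot(radius > 0, length > 0, edge_length > 0)
  disc <- disc_triangulation(radius, edge_length)
  np <- nrow(disc$points)
  nl <- max(1, round(length / axial_edge_length))
  xs <- length * (0:nl) / nl
  V <- cbind(rep(xs, each = np),
             rep(disc$points[, 1], nl + 1),
             rep(disc$points[, 2], nl + 1))
  ntri <- nrow(disc$triangles)
  tets <- matrix(0L, 3 * ntri * nl, 4)
  row <- 1L
  for (k in seq_len(nl)) {
    off0 <- (k - 1L) * np
    for (t in seq_len(ntri)) {
      pr <- c(disc$triangles[t, ] + off0, disc$triangles[t, ] + off0 + np)
      tets[row:(row + 2L), ] <- prism_split(pr)
      row <- row + 3L
    }
  }
  tets <- orient_tets(V, tets)
  bd <- boundary_faces_cpp(V, tets)
  cent <- (V[bd$faces[, 1], ] + V[bd$faces[, 2], ] + V[bd$faces[, 3], ]) / 3
  tags <- rep("wall", nrow(bd$faces))
  tags[abs(cent[, 1]) < 1e-9] <- "inlet"
  tags[abs(cent[, 1] - length) < 1e-9] <- "outlet_1"
  volume_mesh(V, tets, boundary_faces = bd$faces, boundary_owner = bd$owner,
              boundary_tags = tags, h_target = edge_length)
}

#' Build a straight capped tube surface
#'
#' Verification geometry for the flow solver: a circular cylinder with exact
#' planar caps, tagged `inlet` / `outlet_1` / `wall`.
#'
#' @param radius tube radius (mm).
#' @param length tube length (mm); must be at least 12 x `radius` so both
#'   openings satisfy the six-diameter rule.
#' @param mesh_edge_length target edge length (mm).
#' @return a `surface_mesh`.
#' @export
build_straight_tube <- function(radius, length, mesh_edge_length) {
  if (radius <= 0 || length <= 0 || mesh_edge_length <= 0)
    stop("tube dimensions and edge length must be positive")
  if (length < 12 * radius)
    stop("length must be at least 12 x radius ",
         "(openings six diameters from each other)")
  disc <- disc_triangulation(radius, mesh_edge_length)
  np <- nrow(disc$points)
  outer <- disc$outer
  no <- length(outer)
  nl <- max(1, round(length / mesh_edge_length))
  xs <- length * (0:nl) / nl
  # vertex list: disc at x=0, interior rings (outer ring only), disc at x=L
  V <- cbind(0, disc$points)
  ring_ids <- list(outer)
  for (k in 2:nl) {
    ring_ids[[k]] <- nrow(V) + seq_len(no)
    V <- rbind(V, cbind(xs[k], disc$points[outer, , drop = FALSE]))
  }
  top0 <- nrow(V)
  V <- rbind(V, cbind(length, disc$points))
  ring_ids[[nl + 1]] <- top0 + outer
  tris <- disc$triangles[, c(1, 3, 2)]      # inlet cap, outward -x
  tags <- rep("inlet", nrow(tris))
  for (k in seq_len(nl)) {
    a <- ring_ids[[k]]
    b <- ring_ids[[k + 1]]
    a2 <- a[c(2:no, 1)]
    b2 <- b[c(2:no, 1)]
    side <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
    tris <- rbind(tris, side)
    tags <- c(tags, rep("wall", 2 * no))
  }
  tris <- rbind(tris, top0 + disc$triangles)  # outlet cap, outward +x
  tags <- c(tags, rep("outlet_1", nrow(disc$triangles)))
  mesh <- surface_mesh(V, tris, tags)
  attr(mesh, "generator") <- list(kind = "tube", radius = radius,
                                  length = length)
  mesh
}

# ---- synthetic wall shear fixtures ------------------------------------------

#' Configuration for synthetic wall shear stress fixtures
#'
#' @param base_magnitude baseline shear magnitude (Pa).
#' @param low_shear_fraction target fraction of dome area assigned a shear
#'   magnitude far below the low-shear threshold, in `[0, 1]`.
#' @param reversing_fraction target fraction of wall area whose shear vector
#'   flips direction each half-period, in `[0, 1]`.
#' @param period cardiac period (s).
#' @param n_steps number of uniform time samples over one period (>= 2).
#' @param magnitude_jitter relative magnitude perturbation applied to
#'   non-low-shear facets (seeded, deterministic).
#' @param seed integer RNG seed for the jitter.
#' @return a `wall_field_config` list.
#' @export
wall_field_config <- function(base_magnitude = 2, low_shear_fraction = 0,
                              reversing_fraction = 0, period = 1,
                              n_steps = 20L, magnitude_jitter = 0.1,
                              seed = 1L) {
  stopifnot(base_magnitude > 0, period > 0, n_steps >= 2,
            low_shear_fraction >= 0, low_shear_fraction <= 1,
            reversing_fraction >= 0, reversing_fraction <= 1,
            magnitude_jitter >= 0, magnitude_jitter < 0.5)
  structure(as.list(environment()), class = "wall_field_config")
}

# greedy prefix of facets (by index) whose area best matches frac * total
pick_area_fraction <- function(areas, frac) {
  if (frac <= 0) return(logical(length(areas)))
  cum <- cumsum(areas)
  total <- cum[length(cum)]
  k <- which.min(abs(cum - frac * total))
  seq_along(areas) <= k
}

#' Generate a synthetic wall shear stress time series with known indices
#'
#' Constructs a per-facet shear-vector time series on the wall of a mesh in
#' which a chosen area fraction reverses direction each half-period and a
#' chosen fraction of the dome carries a magnitude far below the low-shear
#' threshold. Because magnitudes are constant over the cycle and the time
#' samples are uniform, every index (TAWSS, OSI, LSA and variants) has an
#' exact closed form which is returned alongside the record, so the index
#' kernels can be verified to round-off.
#'
#' @param mesh a `surface_mesh`; facets tagged `dome`/`wall` are used. When
#'   the mesh has no `dome` tags all wall facets are treated as dome and the
#'   low-shear reference defaults to the dome mean.
#' @param config a [wall_field_config()].
#' @return list with elements `record` (a [wall_shear_record()]) and `truth`
#'   (named list of exact index values: per-facet `tawss`, `osi`, `pwss`,
#'   and scalars `lsa`, `talsa`, `ntawss`, `npwss`,
#'   `low_area_fraction`, `reversing_area_fraction`).
#' @export
synth_wall_field <- function(mesh, config) {
  stopifnot(inherits(config, "wall_field_config"))
  keep <- mesh$region_tags %in% c("wall", "dome")
  if (!any(mesh$region_tags == "wall") && !any(mesh$region_tags == "dome"))
    stop("mesh has no wall-tagged facets")
  areas <- triangle_areas(mesh)[keep]
  normals <- triangle_normals(mesh)[keep, , drop = FALSE]
  tags <- mesh$region_tags[keep]
  if (!any(tags == "dome")) tags <- rep("dome", length(tags))
  has_parent <- any(tags == "wall")
  reference <- if (has_parent) "parent" else "dome"
  nf <- length(areas)
  # facet-tangent unit direction: project e_x (fall back to e_y) on the facet
  dirs <- cbind(1 - normals[, 1]^2, -normals[, 1] * normals[, 2],
                -normals[, 1] * normals[, 3])
  bad <- sqrt(rowSums(dirs^2)) < 1e-6
  if (any(bad))
    dirs[bad, ] <- cbind(-normals[bad, 2] * normals[bad, 1],
                         1 - normals[bad, 2]^2,
                         -normals[bad, 2] * normals[bad, 3])
  dirs <- dirs / sqrt(rowSums(dirs^2))

  mag <- rep(config$base_magnitude, nf)
  if (config$magnitude_jitter > 0)
    mag <- mag * with_seed(config$seed,
                           1 + config$magnitude_jitter * runif(nf, -1, 1))
  dome_idx <- which(tags == "dome")
  low_sel_dome <- pick_area_fraction(areas[dome_idx], config$low_shear_fraction)
  low <- rep(FALSE, nf)
  low[dome_idx[low_sel_dome]] <- TRUE
  mag[low] <- 0.05 * config$base_magnitude
  rev_sel <- pick_area_fraction(areas, config$reversing_fraction)

  nt <- config$n_steps
  times <- config$period * (seq_len(nt) - 1) / nt
  sgn <- matrix(1, nf, nt)
  flip <- times >= config$period / 2
  sgn[rev_sel, flip] <- -1
  wss <- array(0, dim = c(nf, 3, nt))
  for (k in seq_len(nt))
    wss[, , k] <- dirs * (mag * sgn[, k])

  record <- wall_shear_record(wss, areas, tags, times, config$period,
                              t_peak = times[1], reference = reference)

  nplus <- sum(!flip)
  osi_rev <- 0.5 * (1 - abs(nplus - (nt - nplus)) / nt)
  osi <- ifelse(rev_sel, osi_rev, 0)
  aw <- function(x, idx) sum(x[idx] * areas[idx]) / sum(areas[idx])
  dome_mean <- aw(mag, dome_idx)
  ref_mean <- if (reference == "parent") aw(mag, which(tags == "wall")) else dome_mean
  thr <- 0.1 * ref_mean
  lsa <- 100 * sum(areas[dome_idx][mag[dome_idx] < thr]) / sum(areas[dome_idx])
  truth <- list(
    tawss = mag, osi = osi, pwss = mag,
    lsa = lsa, plsa = lsa, talsa = lsa,
    ntawss = if (has_parent) 100 * dome_mean / aw(mag, which(tags == "wall")) else NA_real_,
    npwss = if (has_parent) 100 * dome_mean / aw(mag, which(tags == "wall")) else NA_real_,
    low_area_fraction = sum(areas[dome_idx][low_sel_dome]) / sum(areas[dome_idx]),
    reversing_area_fraction = sum(areas[rev_sel]) / sum(areas))
  list(record = record, truth = truth)
}

#' Flat triangulated plate (test and fixture helper)
#'
#' A uniform right-triangle grid on `[0, sx] x [0, sy]` at z = 0, tagged with
#' a single region. The sheet is open, so it is returned without the
#' watertightness check.
#'
#' @param nx,ny grid cells per side.
#' @param sx,sy side lengths (mm).
#' @param tag region tag for all facets.
#' @return a `surface_mesh` (non-watertight sheet).
#' @export
build_flat_plate <- function(nx = 20, ny = 20, sx = 10, sy = 10, tag = "dome") {
  xs <- sx * (0:nx) / nx
  ys <- sy * (0:ny) / ny
  V <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1), 0)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  tris <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  surface_mesh(V, tris, rep(tag, nrow(tris)), validate = FALSE)
}
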