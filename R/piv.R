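#' Line probe for velocity profiles
#'
#' A segment in the PIV measurement plane (parallel to the model base),
#' conventionally with one end on top of the aneurysm dome; sampling also
#' uses the two copies shifted along the plane normal by the microscope's
#' depth of field.
#'
#' @param p1,p2 segment endpoints (mm), lying in the plane.
#' @param plane_point,plane_normal the measurement plane (mm / unit vector).
#' @param dof depth of field of the imaging setup, micrometres
#'   (default 248).
#' @return a `line_probe`.
#' @export
line_probe <- function(p1, p2, plane_point, plane_normal, dof = 248) {
  stopifnot(length(p1) == 3, length(p2) == 3, dof > 0)
  n <- plane_normal / sqrt(sum(plane_normal^2))
  off <- abs(c(sum((p1 - plane_point) * n), sum((p2 - plane_point) * n)))
  if (any(off > 1e-6 * max(1, sqrt(sum((p2 - p1)^2)))))
    stop("probe endpoints do not lie in the measurement plane")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 plane = list(point = as.numeric(plane_point), normal = n),
                 dof = dof),
            class = "line_probe")
}

#' Velocity field wrapper
#'
#' Adapts either a steady `flow_solution` (P1 interpolation on its mesh) or
#' an analytic function to the common interface used by pathline tracing
#' and line sampling: positions in mm in, velocities in m/s out (`NA`
#' outside the domain).
#'
#' @param x a steady `flow_solution`, or a function mapping an n x 3 matrix
#'   of positions (mm) to an n x 3 matrix of velocities (m/s).
#' @return a `velocity_field` (function with class attribute).
#' @export
velocity_field <- function(x) {
  if (inherits(x, "flow_solution")) {
    stopifnot(x$type == "steady")
    loc <- make_locator_cpp(x$mesh$vertices, x$mesh$tets)
    u <- x$u
    f <- function(pts) interp_field_cpp(loc, u, as.matrix(pts))
    attr(f, "mesh") <- x$mesh
  } else if (is.function(x)) {
    f <- function(pts) x(as.matrix(pts))
  } else stop("velocity_field needs a steady flow_solution or a function")
  class(f) <- c("velocity_field", "function")
  f
}

#' Trace massless particle pathlines
#'
#' Integrates `dx/dt = u(x)` through a steady velocity field with an
#' adaptive Runge-Kutta scheme (Dormand-Prince 4(5), relative tolerance
#' 1e-10) over the camera exposure window. Seeds are drawn uniformly within
#' the aneurysm dome (above the neck plane, inside the lumen); seeds
#' falling outside the fluid domain are resampled and counted. Traces that
#' leave the domain are truncated at the last interior sample and flagged.
#'
#' @param field a [velocity_field()] (or steady `flow_solution`).
#' @param n_seeds number of particles.
#' @param exposure exposure window (s), default 0.010.
#' @param seed RNG seed for reproducible seed placement.
#' @param seeds optional n x 3 matrix of seed positions (mm), overriding
#'   random placement.
#' @param n_save stored samples per trace (including the seed).
#' @return a `pathline_set`: list of traces (matrices of mm positions),
#'   sample times, seeds, exposure, and `n_resampled`.
#' @export
trace_pathlines <- function(field, n_seeds = 100, exposure = 0.010,
                            seed = 1L, seeds = NULL, n_save = 26) {
  field <- if (inherits(field, "velocity_field")) field else velocity_field(field)
  n_resampled <- 0L
  if (is.null(seeds)) {
    mesh <- attr(field, "mesh")
    if (is.null(mesh))
      stop("random seeding needs a mesh-backed field; pass explicit seeds")
    seeds <- with_seed(seed, {
      out <- matrix(NA_real_, 0, 3)
      lo <- apply(mesh$vertices, 2, min)
      hi <- apply(mesh$vertices, 2, max)
      np <- mesh$neck_plane
      tries <- 0L
      while (nrow(out) < n_seeds && tries < 1000 * n_seeds) {
        cand <- cbind(stats::runif(n_seeds, lo[1], hi[1]),
                      stats::runif(n_seeds, lo[2], hi[2]),
                      stats::runif(n_seeds, lo[3], hi[3]))
        if (!is.null(np))
          cand <- cand[(cand %*% np$normal)[, 1] > sum(np$point * np$normal), ,
                       drop = FALSE]
        if (nrow(cand)) {
          ok <- !is.na(field(cand)[, 1])
          n_resampled <- n_resampled + sum(!ok)
          out <- rbind(out, cand[ok, , drop = FALSE])
        }
        tries <- tries + n_seeds
      }
      if (nrow(out) < n_seeds)
        stop("could not place ", n_seeds, " seeds inside the dome")
      out[seq_len(n_seeds), , drop = FALSE]
    })
    if (n_resampled > 0)
      message(n_resampled, " candidate seeds fell outside the fluid domain and were resampled")
  } else {
    seeds <- as.matrix(seeds)
  }
  times <- seq(0, exposure, length.out = n_save)
  # velocities are m/s, positions mm: dx/dt = 1000 * u
  rhs <- function(t, y, parms) {
    v <- field(matrix(y, 1, 3))
    if (anyNA(v)) v <- matrix(0, 1, 3)
    list(as.numeric(v) * 1000)
  }
  traces <- vector("list", nrow(seeds))
  exited <- logical(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    sol <- deSolve::ode(y = seeds[i, ], times = times, func = rhs,
                        parms = NULL, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    pos <- unname(sol[, 2:4, drop = FALSE])
    inside <- !is.na(field(pos)[, 1])
    if (!all(inside)) {
      last <- max(1, which.min(inside) - 1)  # first exit, keep up to it
      pos <- pos[seq_len(last), , drop = FALSE]
      exited[i] <- TRUE
    }
    traces[[i]] <- pos
  }
  structure(list(seeds = seeds, traces = traces, times = times,
                 exposure = exposure, exited = exited,
                 depth_code = NULL, n_resampled = n_resampled),
            class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  cat("pathline_set:", length(x$traces), "traces over",
      x$exposure * 1000, "ms exposure\n")
  if (!is.null(x$depth_code)) cat("  focal-band filtered\n")
  invisible(x)
}

#' Filter pathlines to the focal band
#'
#' Keeps traces whose midpoint lies within half the depth of field of the
#' measurement plane and attaches a normalized depth code in `[0, 1]`
#' (0 on the mid-plane, 1 at the band edge), the greyscale convention of
#' PIV trace renderings.
#'
#' @param paths a `pathline_set`.
#' @param plane list with `point` (mm) and `normal` (unit).
#' @param dof depth of field, micrometres.
#' @param rule band membership by trace `"midpoint"` (default) or by the
#'   `"whole"` trace (every sample within the band).
#' @return the filtered `pathline_set` with `depth_code` attached.
#' @export
render_focal_band <- function(paths, plane, dof = 248,
                              rule = c("midpoint", "whole")) {
  stopifnot(dof > 0)
  rule <- match.arg(rule)
  n <- plane$normal / sqrt(sum(plane$normal^2))
  half_mm <- dof / 2000  # um -> mm
  depth_of <- function(tr, reduce) {
    dd <- abs((tr - matrix(plane$point, nrow(tr), 3, byrow = TRUE)) %*% n)
    reduce(dd)
  }
  d <- vapply(paths$traces, function(tr)
    depth_of(tr[ceiling(nrow(tr) / 2), , drop = FALSE], max), numeric(1))
  dmax <- if (rule == "whole")
    vapply(paths$traces, depth_of, numeric(1), reduce = max) else d
  keep <- dmax <= half_mm
  out <- paths
  out$seeds <- paths$seeds[keep, , drop = FALSE]
  out$traces <- paths$traces[keep]
  out$exited <- paths$exited[keep]
  out$depth_code <- if (is.finite(half_mm)) d[keep] / half_mm else rep(0, sum(keep))
  out
}

#' Sample velocity magnitude along a probe line
#'
#' Evaluates the velocity magnitude at `n_points` along the probe segment
#' and along its two copies shifted by plus/minus the depth of field along
#' the plane normal. Points outside the lumen are `NA`.
#'
#' @param solution a steady `flow_solution` (or [velocity_field()]).
#' @param probe a [line_probe()].
#' @param n_points samples along the line.
#' @return data.frame with `position_mm` (arc length from `p1`), `band`
#'   (`mid` / `upper` / `lower`) and `velocity_m_s`.
#' @export
sample_velocity_line <- function(solution, probe, n_points = 100) {
  field <- if (inherits(solution, "velocity_field")) solution
           else velocity_field(solution)
  s <- seq(0, 1, length.out = n_points)
  base <- outer(1 - s, probe$p1) + outer(s, probe$p2)
  shift <- probe$plane$normal * probe$dof / 1000  # um -> mm
  arc <- s * sqrt(sum((probe$p2 - probe$p1)^2))
  bands <- list(mid = 0, upper = 1, lower = -1)
  out <- do.call(rbind, lapply(names(bands), function(b) {
    pts <- base + matrix(shift * bands[[b]], n_points, 3, byrow = TRUE)
    v <- field(pts)
    data.frame(position_mm = arc, band = b,
               velocity_m_s = sqrt(rowSums(v^2)))
  }))
  if (all(is.na(out$velocity_m_s)))
    stop("entire probe line lies outside the lumen")
  out
}

#' Kinematic similarity between two fluids
#'
#' Reynolds similarity at fixed geometry and flux holds when the
#' density-to-viscosity ratios agree; this is how a glycerin-water
#' circulating medium is matched to blood.
#'
#' @param fluid_a,fluid_b [fluid_properties()] pairs.
#' @param tolerance relative ratio tolerance (default 1 percent).
#' @return list with `ratio_a`, `ratio_b` (s m^-2) and logical `similar`.
#' @export
check_kinematic_similarity <- function(fluid_a, fluid_b, tolerance = 0.01) {
  ra <- fluid_a$density / fluid_a$dynamic_viscosity
  rb <- fluid_b$density / fluid_b$dynamic_viscosity
  list(ratio_a = ra, ratio_b = rb,
       similar = abs(ra - rb) / max(ra, rb) <= tolerance)
}

#' Export pathlines as VTP polylines
#'
#' @param paths a `pathline_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pathlines_vtp <- function(paths, path) {
  allpts <- do.call(rbind, paths$traces)
  npts <- vapply(paths$traces, nrow, integer(1))
  offs <- cumsum(npts)
  depth <- if (is.null(paths$depth_code)) rep(0, length(npts)) else paths$depth_code
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">', con)
  writeLines('<PolyData>', con)
  writeLines(sprintf('<Piece NumberOfPoints="%d" NumberOfLines="%d">',
                     nrow(allpts), length(npts)), con)
  writeLines('<Points>', con)
  xml_data_array(con, "Points", as.vector(t(allpts)), 3)
  writeLines('</Points>', con)
  writeLines('<Lines>', con)
  xml_data_array(con, "connectivity", seq_len(nrow(allpts)) - 1L, 1, "Int32")
  xml_data_array(con, "offsets", offs, 1, "Int32")
  writeLines('</Lines>', con)
  writeLines('<PointData>', con)
  xml_data_array(con, "depth_code", rep(depth, npts), 1)
  writeLines('</PointData>', con)
  writeLines('</Piece>', con)
  writeLines('</PolyData>', con)
  writeLines('</VTKFile>', con)
  invisible(path)
}
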