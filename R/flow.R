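#' Fluid properties
#'
#' Defaults are the blood model used throughout: constant dynamic viscosity
#' 3.5 mPa s and density 1050 kg m^-3.
#'
#' @param dynamic_viscosity Pa s.
#' @param density kg m^-3.
#' @return a `fluid_properties` list.
#' @export
fluid_properties <- function(dynamic_viscosity = 3.5e-3, density = 1050) {
  stopifnot(dynamic_viscosity > 0, density > 0)
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' Inflow waveform from PSV / EDV / TAV constraints
#'
#' Builds a smooth periodic mean-velocity curve pinned by its maximum (peak
#' systolic velocity), minimum (end diastolic velocity) and period mean
#' (time-averaged velocity). The shape is a raised-cosine systolic pulse on
#' a diastolic plateau whose width is solved in closed form so the period
#' mean equals TAV exactly; when the mean sits above the PSV/EDV midpoint
#' the construction flips to a raised-cosine diastolic dip. The three
#' constraints are re-verified numerically on return (trapezoid quadrature,
#' relative tolerance 1e-3). Sampled waveforms may be supplied instead via
#' `samples` (two-column time/velocity data over one period).
#'
#' @param psv,edv,tav peak systolic, end diastolic and time-averaged mean
#'   inlet velocity (m/s); requires `edv <= tav <= psv`.
#' @param heart_rate beats per minute; the period is `60 / heart_rate` s.
#' @param t_peak_frac position of the systolic peak within the cycle
#'   (fraction of the period).
#' @param samples optional data.frame / matrix with columns time (s) and
#'   velocity (m/s) covering one period; overrides the analytic shape.
#' @return an `inflow_waveform` with fields `fun` (vectorized w(t)), `psv`,
#'   `edv`, `tav`, `period`, `t_peak`.
#' @export
make_waveform <- function(psv, edv, tav, heart_rate = 60,
                          t_peak_frac = 0.25, samples = NULL) {
  if (!(edv <= tav && tav <= psv) || edv < 0)
    stop("infeasible waveform constraints: need 0 <= EDV <= TAV <= PSV")
  period <- 60 / heart_rate
  t_peak <- t_peak_frac * period
  if (!is.null(samples)) {
    samples <- as.matrix(samples)
    fun <- make_periodic_interp(samples[, 1], samples[, 2], period)
    t_peak <- samples[which.max(samples[, 2]), 1]
  } else if (psv == edv) {
    fun <- function(t) rep(psv, length(t))
  } else {
    frac <- (tav - edv) / (psv - edv)
    if (frac <= 0.5) {
      width <- 2 * frac * period
      fun <- function(t) {
        d <- abs((t - t_peak + period / 2) %% period - period / 2)
        edv + (psv - edv) * ifelse(d < width / 2,
                                   0.5 * (1 + cos(2 * pi * d / width)), 0)
      }
    } else {
      width <- 2 * (1 - frac) * period
      t_dip <- (t_peak + period / 2) %% period
      fun <- function(t) {
        d <- abs((t - t_dip + period / 2) %% period - period / 2)
        psv - (psv - edv) * ifelse(d < width / 2,
                                   0.5 * (1 + cos(2 * pi * d / width)), 0)
      }
    }
  }
  wf <- structure(list(fun = fun, psv = psv, edv = edv, tav = tav,
                       period = period, t_peak = t_peak),
                  class = "inflow_waveform")
  verify_waveform(wf)
  wf
}

make_periodic_interp <- function(t, v, period) {
  ord <- order(t %% period)
  t <- (t %% period)[ord]
  v <- v[ord]
  tt <- c(t, t[1] + period)
  vv <- c(v, v[1])
  function(q) stats::approx(tt, vv, xout = q %% period, rule = 2)$y
}

verify_waveform <- function(wf, n = 4001) {
  t <- wf$period * (0:(n - 1)) / (n - 1)
  w <- wf$fun(t)
  if (any(w < 0)) stop("waveform takes negative values")
  mean_w <- (sum(w) - (w[1] + w[n]) / 2) / (n - 1)
  chk <- function(got, want, what) {
    if (want != 0 && abs(got - want) / abs(want) > 1e-3)
      stop(sprintf("waveform %s constraint violated: %.5f vs %.5f",
                   what, got, want))
  }
  chk(max(w), wf$psv, "PSV")
  chk(min(w), wf$edv, "EDV")
  chk(mean_w, wf$tav, "TAV")
  invisible(wf)
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf("inflow_waveform: PSV %.3g, EDV %.3g, TAV %.3g m/s, period %.3g s (peak at %.3g s)\n",
              x$psv, x$edv, x$tav, x$period, x$t_peak))
  invisible(x)
}

#' Inlet volumetric flux from radius and mean velocity
#'
#' `flux = TAV * pi R^2`, reported in mL/min to the nearest integer, the
#' convention of the inlet table.
#'
#' @param radius_mm inlet radius (mm).
#' @param tav time-averaged mean inlet velocity (m/s).
#' @return flux in mL/min, rounded to the nearest integer.
#' @export
compute_inlet_flux <- function(radius_mm, tav) {
  stopifnot(radius_mm > 0)
  round(tav * pi * (radius_mm * 1e-3)^2 * 6e7)
}

#' Mean inlet velocity from volumetric flux
#'
#' Inverse of [compute_inlet_flux()], reported to two decimals.
#'
#' @param radius_mm inlet radius (mm).
#' @param flux_ml_min volumetric flux (mL/min).
#' @return TAV in m/s, rounded to 2 decimals.
#' @export
tav_from_flux <- function(radius_mm, flux_ml_min) {
  stopifnot(radius_mm > 0)
  round(flux_ml_min / 6e7 / (pi * (radius_mm * 1e-3)^2), 2)
}

#' Assemble a flow case
#'
#' Bundles the volume mesh, fluid, inflow waveform and discretization
#' parameters. The time step is snapped to an integer divisor of the
#' period; the effective inlet radius is measured from the tagged inlet cap
#' area and stored in the case.
#'
#' @param mesh a `volume_mesh` with `inlet` and `outlet_*` boundary tags.
#' @param fluid a [fluid_properties()].
#' @param waveform an [make_waveform()] result.
#' @param dt time step (s); default period / 200.
#' @param n_cycles number of cardiac cycles (statistics use the final one).
#' @param bdf_order temporal order, 1 or 2.
#' @return a `flow_case`.
#' @export
flow_case <- function(mesh, fluid = fluid_properties(),
                      waveform = make_waveform(0.45, 0.2, 0.3, 60),
                      dt = waveform$period / 200, n_cycles = 2L,
                      bdf_order = 2L) {
  stopifnot(inherits(mesh, "volume_mesh"), n_cycles >= 1,
            bdf_order %in% c(1L, 2L))
  nsteps <- round(waveform$period / dt)
  if (nsteps < 2) stop("time step too large for the period")
  dt <- waveform$period / nsteps
  inlet <- inlet_geometry(mesh)
  structure(list(mesh = mesh, fluid = fluid, waveform = waveform, dt = dt,
                 n_cycles = as.integer(n_cycles),
                 bdf_order = as.integer(bdf_order),
                 inlet_radius = inlet$radius),
            class = "flow_case")
}

# inlet cap geometry in mm: area centroid, inward unit axis, effective radius
inlet_geometry <- function(mesh) {
  sel <- which(mesh$boundary$tags == "inlet")
  if (length(sel) == 0) stop("mesh has no inlet-tagged boundary faces")
  ar <- boundary_face_areas(mesh)[sel]
  nrm <- boundary_face_normals(mesh)[sel, , drop = FALSE]
  f <- mesh$boundary$faces[sel, , drop = FALSE]
  cent <- (mesh$vertices[f[, 1], , drop = FALSE] +
             mesh$vertices[f[, 2], , drop = FALSE] +
             mesh$vertices[f[, 3], , drop = FALSE]) / 3
  axis_out <- colSums(nrm * ar)
  axis_out <- axis_out / sqrt(sum(axis_out^2))
  list(center = colSums(cent * ar) / sum(ar), inward = -axis_out,
       outward = axis_out, area = sum(ar), radius = sqrt(sum(ar) / pi),
       faces = sel)
}

# Dirichlet data in SI units: no-slip nodes plus a parabolic inlet profile
# scaled so its discrete flux equals target_flux_m3s at unit scale
build_dirichlet <- function(mesh, target_flux_m3s) {
  tags <- mesh$boundary$tags
  noslip_f <- which(!grepl("^(inlet|outlet)", tags))
  inlet <- inlet_geometry(mesh)
  fb <- mesh$boundary$faces
  noslip_nodes <- sort(unique(as.vector(fb[noslip_f, , drop = FALSE])))
  inlet_nodes <- setdiff(sort(unique(as.vector(fb[inlet$faces, , drop = FALSE]))),
                         noslip_nodes)
  rel <- mesh$vertices[inlet_nodes, , drop = FALSE] -
    matrix(inlet$center, length(inlet_nodes), 3, byrow = TRUE)
  ax <- rel %*% inlet$inward
  r2 <- rowSums(rel^2) - ax^2
  prof <- pmax(0, 2 * (1 - r2 / inlet$radius^2))  # unit mean velocity
  base <- outer(as.vector(prof), inlet$inward)
  # discrete flux of the base profile over the inlet facets (m^3/s)
  nodeval <- matrix(0, nrow(mesh$vertices), 3)
  nodeval[inlet_nodes, ] <- base
  q <- discrete_flux(mesh, nodeval, inlet$faces, inward = TRUE)
  base <- base * (target_flux_m3s / q)
  dir_nodes <- c(noslip_nodes, inlet_nodes)
  dir_base <- rbind(matrix(0, length(noslip_nodes), 3), base)
  # lumped wall mass (m^2) for consistent traction recovery
  wf_areas <- boundary_face_areas(mesh)[noslip_f] * 1e-6
  wmass <- rep(0, nrow(mesh$vertices))
  for (k in 1:3) {
    add <- rowsum(wf_areas / 3, fb[noslip_f, k], reorder = FALSE)
    wmass[as.integer(rownames(add))] <- wmass[as.integer(rownames(add))] + add
  }
  list(dir_nodes = dir_nodes, dir_base = dir_base,
       wall_nodes = noslip_nodes, wall_mass = wmass[noslip_nodes],
       noslip_faces = noslip_f, inlet = inlet)
}

# flux of a nodal velocity field (m/s) through boundary faces (areas in mm^2
# converted to m^2); inward = TRUE counts flow entering the domain positive
discrete_flux <- function(mesh, nodal_u, faces, inward = FALSE) {
  ar <- boundary_face_areas(mesh)[faces] * 1e-6
  nrm <- boundary_face_normals(mesh)[faces, , drop = FALSE]
  if (inward) nrm <- -nrm
  f <- mesh$boundary$faces[faces, , drop = FALSE]
  un <- (rowSums(nodal_u[f[, 1], , drop = FALSE] * nrm) +
           rowSums(nodal_u[f[, 2], , drop = FALSE] * nrm) +
           rowSums(nodal_u[f[, 3], , drop = FALSE] * nrm)) / 3
  sum(un * ar)
}

#' Steady incompressible flow
#'
#' Solves the stationary Navier-Stokes equations by Picard (Oseen)
#' iteration with a parabolic inlet profile scaled to the requested
#' volumetric flux, no-slip walls and zero-traction outlets. Wall traction
#' is recovered by the consistent-flux method and stored with the solution.
#'
#' @param case a [flow_case()].
#' @param flux_ml_min inlet flux (mL/min).
#' @param tol Picard convergence tolerance (relative max-norm change).
#'   Continuity is enforced exactly at every sweep (direct solves), so mass
#'   balance does not depend on this tolerance.
#' @param max_iter maximum Picard sweeps.
#' @param relax initial under-relaxation of the advecting field (reduced
#'   adaptively when the iteration stops contracting).
#' @return a `flow_solution` (steady).
#' @export
solve_steady <- function(case, flux_ml_min, tol = 1e-5, max_iter = 40,
                         relax = 1.0) {
  stopifnot(inherits(case, "flow_case"))
  mesh <- case$mesh
  q <- flux_ml_min / 6e7
  bc <- build_dirichlet(mesh, q)
  res <- ns_solve_cpp(mesh$vertices * 1e-3, mesh$tets,
                      case$fluid$dynamic_viscosity, case$fluid$density,
                      as.integer(bc$dir_nodes - 1L), bc$dir_base,
                      TRUE, numeric(0), 0, 2L, 0L, tol, as.integer(max_iter),
                      relax, as.integer(bc$wall_nodes - 1L), bc$wall_mass)
  if (res$iterations >= max_iter && utils::tail(res$change, 1) > tol)
    warning(sprintf("Picard iteration did not converge: residual %.2e after %d sweeps",
                    utils::tail(res$change, 1), res$iterations))
  structure(list(type = "steady", mesh = mesh, case = case,
                 fluid = case$fluid, flux_ml_min = flux_ml_min,
                 u = res$u, p = res$p,
                 traction = res$traction, wall_nodes = bc$wall_nodes,
                 noslip_faces = bc$noslip_faces,
                 iterations = res$iterations, change = res$change),
            class = "flow_solution")
}

#' Pulsatile incompressible flow
#'
#' BDF time stepping (order 1 or 2) with linearly implicit convection (the
#' advecting field is the BDF extrapolation of previous steps). The run
#' starts from rest with the waveform ramped over the first tenth of the
#' first cycle; velocity, pressure and recovered wall traction of every
#' step of the final cycle are stored.
#'
#' @param case a [flow_case()].
#' @return a `flow_solution` (pulsatile).
#' @export
solve_pulsatile <- function(case) {
  stopifnot(inherits(case, "flow_case"), case$n_cycles >= 1)
  mesh <- case$mesh
  wf <- case$waveform
  q_tav <- wf$tav * pi * (inlet_geometry(mesh)$radius * 1e-3)^2
  bc <- build_dirichlet(mesh, q_tav)
  nsteps_cycle <- round(wf$period / case$dt)
  total <- nsteps_cycle * case$n_cycles
  tk <- case$dt * seq_len(total)
  ramp <- pmin(1, tk / (0.1 * wf$period))
  scale <- wf$fun(tk) / wf$tav * ramp
  store_from <- total - nsteps_cycle
  res <- ns_solve_cpp(mesh$vertices * 1e-3, mesh$tets,
                      case$fluid$dynamic_viscosity, case$fluid$density,
                      as.integer(bc$dir_nodes - 1L), bc$dir_base,
                      FALSE, scale, case$dt, case$bdf_order,
                      as.integer(store_from), 0, 0L, 1.0,
                      as.integer(bc$wall_nodes - 1L), bc$wall_mass)
  times_cycle <- tk[(store_from + 1):total] - (case$n_cycles - 1) * wf$period
  structure(list(type = "pulsatile", mesh = mesh, case = case,
                 fluid = case$fluid,
                 u_steps = res$u_steps, p_steps = res$p_steps,
                 traction_steps = res$traction_steps,
                 wall_nodes = bc$wall_nodes, noslip_faces = bc$noslip_faces,
                 times = times_cycle, period = wf$period,
                 kinetic_energy = res$kinetic_energy),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution (", x$type, "), mesh: ", nrow(x$mesh$vertices),
      " vertices\n", sep = "")
  if (x$type == "steady")
    cat(sprintf("  flux %.1f mL/min, %d Picard sweeps\n",
                x$flux_ml_min, x$iterations))
  else
    cat(sprintf("  %d stored steps over one period of %.3g s\n",
                length(x$u_steps), x$period))
  invisible(x)
}

#' Boundary fluxes of a flow solution
#'
#' Volumetric flux through each boundary tag (outward positive, m^3/s and
#' mL/min), evaluated from the discrete velocity by facet quadrature.
#'
#' @param solution a `flow_solution`.
#' @param step final-cycle step index (pulsatile only).
#' @return data.frame with one row per boundary tag plus a mass-balance row
#'   (`net`).
#' @export
boundary_flux <- function(solution, step = NULL) {
  mesh <- solution$mesh
  u <- if (solution$type == "steady") solution$u else solution$u_steps[[step]]
  tags <- unique(mesh$boundary$tags)
  qs <- vapply(tags, function(tg)
    discrete_flux(mesh, u, which(mesh$boundary$tags == tg)), numeric(1))
  out <- data.frame(tag = c(tags, "net"),
                    flux_m3_s = c(qs, sum(qs)))
  out$flux_ml_min <- out$flux_m3_s * 6e7
  out
}

#' Dome-averaged solution quantities
#'
#' Velocity magnitude is volume-averaged over the tetrahedra of the dome
#' region; pressure and wall shear stress magnitude are area-averaged over
#' dome-tagged boundary facets. For generator-produced meshes the dome
#' region is the sac volume on the dome side of the neck plane and outside
#' the parent vessel (a fixed geometric region, stable under re-meshing);
#' for imported meshes it falls back to everything above the neck plane.
#'
#' @param solution a steady `flow_solution` on a mesh with a neck plane.
#' @return named numeric vector: `velocity` (m/s), `pressure` (Pa),
#'   `wss` (Pa).
#' @export
dome_averages <- function(solution) {
  mesh <- solution$mesh
  np <- mesh$neck_plane
  if (is.null(np)) stop("mesh has no neck plane; dome region undefined")
  stopifnot(solution$type == "steady")
  cent <- (mesh$vertices[mesh$tets[, 1], ] + mesh$vertices[mesh$tets[, 2], ] +
             mesh$vertices[mesh$tets[, 3], ] + mesh$vertices[mesh$tets[, 4], ]) / 4
  above <- (cent %*% np$normal)[, 1] > sum(np$point * np$normal)
  geom <- mesh$generator_geom
  if (!is.null(geom)) {
    vessel <- geom$prims[-geom$dome_rows, , drop = FALSE]
    above <- above & prim_phi_cpp(vessel, cent) > 0
  }
  if (!any(above)) stop("no tetrahedra in the dome region")
  vols <- tet_volumes(mesh$vertices, mesh$tets)[above]
  uc <- (solution$u[mesh$tets[above, 1], , drop = FALSE] +
           solution$u[mesh$tets[above, 2], , drop = FALSE] +
           solution$u[mesh$tets[above, 3], , drop = FALSE] +
           solution$u[mesh$tets[above, 4], , drop = FALSE]) / 4
  vel <- sum(sqrt(rowSums(uc^2)) * vols) / sum(vols)
  dome_f <- which(mesh$boundary$tags == "dome")
  if (length(dome_f) == 0) stop("no dome-tagged boundary facets")
  ar <- boundary_face_areas(mesh)[dome_f]
  fb <- mesh$boundary$faces[dome_f, , drop = FALSE]
  pf <- (solution$p[fb[, 1]] + solution$p[fb[, 2]] + solution$p[fb[, 3]]) / 3
  pres <- sum(pf * ar) / sum(ar)
  rec <- extract_wss(solution)
  dome_r <- rec$tags == "dome"
  wss <- sum(compute_tawss(rec)[dome_r] * rec$areas[dome_r]) /
    sum(rec$areas[dome_r])
  c(velocity = vel, pressure = pres, wss = wss)
}

#' Mesh dependency test
#'
#' Re-meshes the surface at three decreasing edge lengths, solves steady
#' flow at the given inlet flux on each, and tabulates dome-averaged
#' velocity magnitude, pressure and wall shear stress. Convergence is
#' flagged when the dome-averaged velocities of the two finest meshes agree
#' within 2 percent. Solve failures leave the remaining rows `NA` so the
#' partial table is still returned.
#'
#' @param surface a tagged `surface_mesh` (with neck plane).
#' @param edge_lengths three decreasing target edge lengths (mm).
#' @param flux_ml_min steady inlet flux (mL/min), default 169.
#' @param fluid a [fluid_properties()].
#' @return data.frame with columns `h`, `velocity`, `pressure`, `wss` and a
#'   `converged` attribute.
#' @export
mesh_dependency_test <- function(surface, edge_lengths, flux_ml_min = 169,
                                 fluid = fluid_properties()) {
  stopifnot(length(edge_lengths) == 3, all(diff(edge_lengths) < 0))
  out <- data.frame(h = rep(NA_real_, 3), velocity = NA_real_,
                    pressure = NA_real_, wss = NA_real_)
  for (i in 1:3) {
    ok <- tryCatch({
      vm <- tetrahedralize(surface, edge_lengths[i])
      case <- flow_case(vm, fluid = fluid)
      sol <- solve_steady(case, flux_ml_min)
      av <- dome_averages(sol)
      out$h[i] <- vm$h
      out$velocity[i] <- av["velocity"]
      out$pressure[i] <- av["pressure"]
      out$wss[i] <- av["wss"]
      TRUE
    }, error = function(e) {
      warning("mesh dependency stage ", i, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) break
  }
  attr(out, "converged") <- isTRUE(
    abs(out$velocity[2] - out$velocity[3]) / out$velocity[3] < 0.02)
  out
}
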