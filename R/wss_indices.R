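#' Wall shear stress record
#'
#' Per-facet wall shear stress vectors over one cardiac cycle, with facet
#' areas and region tags. All index kernels
#' ([compute_tawss()], [compute_osi()], [compute_lsa()], ...) operate on
#' this container, whether it came from a flow solution or from the
#' synthetic fixture generator.
#'
#' @param wss numeric array (facets x 3 x time samples), Pa.
#' @param areas facet areas (mm^2).
#' @param tags facet region tags (`dome` / `wall` / others).
#' @param times sample times (s) within one period, strictly increasing.
#' @param period cycle duration T (s).
#' @param t_peak time of the systolic peak within the cycle (s).
#' @param reference default low-shear-area reference region, `"parent"`
#'   (the vessel wall) or `"dome"`.
#' @return a `wall_shear_record`.
#' @export
wall_shear_record <- function(wss, areas, tags, times, period,
                              t_peak = times[1], reference = c("parent", "dome")) {
  reference <- match.arg(reference)
  if (length(dim(wss)) != 3 || dim(wss)[2] != 3)
    stop("wss must be a facets x 3 x time array")
  stopifnot(dim(wss)[1] == length(areas), length(tags) == length(areas),
            dim(wss)[3] == length(times), period > 0,
            !is.unsorted(times), max(times) - min(times) < period)
  structure(list(wss = wss, areas = areas, tags = as.character(tags),
                 times = times, period = period, t_peak = t_peak,
                 reference = reference),
            class = "wall_shear_record")
}

#' @export
print.wall_shear_record <- function(x, ...) {
  cat("wall_shear_record:", dim(x$wss)[1], "facets,", length(x$times),
      "time samples over", x$period, "s\n")
  invisible(x)
}

# periodic trapezoid weights: integral over one period of a periodically
# extended piecewise-linear signal sampled at `times`
time_weights <- function(times, period) {
  n <- length(times)
  if (n == 1) return(period)
  gaps <- diff(c(times, times[1] + period))
  (gaps + c(gaps[n], gaps[-n])) / 2
}

# facet x time matrix of |wss| (shape-stable for single facets / samples)
wss_magnitudes <- function(record) {
  w <- record$wss
  m2 <- w[, 1, , drop = FALSE]^2 + w[, 2, , drop = FALSE]^2 +
    w[, 3, , drop = FALSE]^2
  matrix(sqrt(m2), dim(w)[1], dim(w)[3])
}

# facet x time matrix of one wss component
wss_component <- function(record, c) {
  matrix(record$wss[, c, , drop = FALSE], dim(record$wss)[1],
         dim(record$wss)[3])
}

#' Time-averaged wall shear stress
#'
#' Pointwise `TAWSS = (1/T) \int |wss| dt` with periodic trapezoid
#' quadrature over the stored samples.
#'
#' @param record a [wall_shear_record()].
#' @return numeric vector, one value (Pa) per facet.
#' @export
compute_tawss <- function(record) {
  m <- wss_magnitudes(record)
  w <- time_weights(record$times, record$period)
  as.vector(m %*% w) / record$period
}

#' Oscillatory shear index
#'
#' `OSI = (1/2) (1 - |\int wss dt| / \int |wss| dt)`, zero where the shear
#' vanishes over the whole cycle; values lie in `[0, 0.5]` with 0.5 for
#' perfectly reversing shear.
#'
#' @param record a [wall_shear_record()].
#' @return numeric vector per facet, dimensionless.
#' @export
compute_osi <- function(record) {
  nt <- length(record$times)
  if (nt == 1) return(rep(0, dim(record$wss)[1]))
  w <- time_weights(record$times, record$period)
  vx <- wss_component(record, 1) %*% w
  vy <- wss_component(record, 2) %*% w
  vz <- wss_component(record, 3) %*% w
  num <- sqrt(vx^2 + vy^2 + vz^2)
  den <- wss_magnitudes(record) %*% w
  osi <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(as.vector(osi), 0), 0.5)
}

#' Peak-systole wall shear stress
#'
#' `PWSS` is the shear magnitude at the stored sample nearest the time of
#' the peak systolic velocity (cyclic distance).
#'
#' @param record a [wall_shear_record()].
#' @param t_peak peak time (s); defaults to the record's.
#' @return list with `pwss` (numeric per facet, Pa) and `time` (the sample
#'   used).
#' @export
compute_peak_quantities <- function(record, t_peak = record$t_peak) {
  if (t_peak < 0 || t_peak > record$period)
    stop("peak time ", t_peak, " s outside the sampled cycle [0, ",
         record$period, "]")
  d <- abs(record$times - t_peak)
  d <- pmin(d, record$period - d)
  k <- which.min(d)
  list(pwss = wss_magnitudes(record)[, k], time = record$times[k])
}

region_indices <- function(record, region) {
  idx <- which(record$tags == region)
  if (length(idx) == 0 && region == "dome") idx <- seq_along(record$tags)
  idx
}

#' Low shear area
#'
#' Percentage of the dome area where the shear magnitude falls below
#' `threshold_frac` (default 10 percent) of the spatially averaged shear
#' over the reference region. `mode = "peak"` evaluates at the systolic
#' peak (PLSA); `mode = "time_averaged"` integrates the instantaneous low
#' shear area over the cycle (TALSA), with the instantaneous threshold.
#'
#' @param record a [wall_shear_record()].
#' @param mode `"peak"` or `"time_averaged"`.
#' @param reference `"parent"` (vessel wall mean, the default convention)
#'   or `"dome"`.
#' @param threshold_frac threshold as a fraction of the reference mean.
#' @return percentage in `[0, 100]`.
#' @export
compute_lsa <- function(record, mode = c("peak", "time_averaged"),
                        reference = record$reference, threshold_frac = 0.1) {
  mode <- match.arg(mode)
  dome <- which(record$tags == "dome")
  if (length(dome) == 0) stop("record has no dome-tagged facets")
  ref <- if (identical(reference, "parent")) which(record$tags == "wall") else dome
  if (length(ref) == 0) ref <- dome
  m <- wss_magnitudes(record)
  adome <- record$areas[dome]
  aref <- record$areas[ref]
  lsa_at <- function(k) {
    thr <- threshold_frac * sum(m[ref, k] * aref) / sum(aref)
    100 * sum(adome[m[dome, k] < thr]) / sum(adome)
  }
  if (mode == "peak") {
    d <- abs(record$times - record$t_peak)
    d <- pmin(d, record$period - d)
    lsa_at(which.min(d))
  } else {
    w <- time_weights(record$times, record$period)
    sum(vapply(seq_along(record$times), lsa_at, numeric(1)) * w) / record$period
  }
}

#' Dome indices normalized by the parent artery
#'
#' `NTAWSS` (`NPWSS`) is the area-weighted dome average of TAWSS (PWSS)
#' as a percentage of the parent-artery average.
#'
#' @param record a [wall_shear_record()] with both `dome` and `wall` tags.
#' @return named vector `c(ntawss, npwss)` in percent.
#' @export
compute_normalized <- function(record) {
  dome <- which(record$tags == "dome")
  wall <- which(record$tags == "wall")
  if (length(dome) == 0 || length(wall) == 0)
    stop("normalized indices need both dome and wall (parent) regions")
  tawss <- compute_tawss(record)
  pwss <- compute_peak_quantities(record)$pwss
  aw <- function(x, idx) sum(x[idx] * record$areas[idx]) / sum(record$areas[idx])
  pt <- aw(tawss, wall)
  pp <- aw(pwss, wall)
  if (pt == 0 || pp == 0) stop("parent-artery average shear is zero")
  c(ntawss = 100 * aw(tawss, dome) / pt, npwss = 100 * aw(pwss, dome) / pp)
}

#' Area-weighted region average / maximum of a facet field
#'
#' @param field numeric vector, one value per facet.
#' @param areas facet areas.
#' @param tags facet region tags.
#' @param region tag naming the region.
#' @return scalar.
#' @export
region_average <- function(field, areas, tags, region) {
  idx <- which(tags == region)
  if (length(idx) == 0) stop("region '", region, "' is empty")
  sum(field[idx] * areas[idx]) / sum(areas[idx])
}

#' @rdname region_average
#' @export
region_max <- function(field, areas, tags, region) {
  idx <- which(tags == region)
  if (length(idx) == 0) stop("region '", region, "' is empty")
  max(field[idx])
}

#' Extract the wall shear stress record from a flow solution
#'
#' Wall traction recovered during the solve (consistent-flux method) is
#' averaged per wall facet, projected onto the facet plane and flipped to
#' the stress exerted by the fluid on the wall, giving the WSS vector per
#' facet and stored time step.
#'
#' @param solution a `flow_solution`.
#' @param fluid fluid properties (already embedded in the solution; kept
#'   for interface completeness).
#' @return a [wall_shear_record()].
#' @export
extract_wss <- function(solution, fluid = solution$fluid) {
  mesh <- solution$mesh
  wf_idx <- solution$noslip_faces
  if (length(wf_idx) == 0) stop("solution mesh has no wall-tagged boundary")
  fb <- mesh$boundary$faces[wf_idx, , drop = FALSE]
  areas <- boundary_face_areas(mesh)[wf_idx]
  nrm <- boundary_face_normals(mesh)[wf_idx, , drop = FALSE]
  tags <- mesh$boundary$tags[wf_idx]
  node_row <- match(fb, solution$wall_nodes)
  dim(node_row) <- dim(fb)
  tr_list <- if (solution$type == "steady") list(solution$traction)
             else solution$traction_steps
  nt <- length(tr_list)
  wss <- array(0, dim = c(nrow(fb), 3, nt))
  for (k in seq_len(nt)) {
    tr <- tr_list[[k]]
    tf <- (tr[node_row[, 1], , drop = FALSE] + tr[node_row[, 2], , drop = FALSE] +
             tr[node_row[, 3], , drop = FALSE]) / 3
    # fluid-on-wall stress, tangential part
    tn <- rowSums(tf * nrm)
    wss[, , k] <- -(tf - tn * nrm)
  }
  if (solution$type == "steady") {
    wall_shear_record(wss, areas, tags, times = 0, period = 1, t_peak = 0)
  } else {
    wall_shear_record(wss, areas, tags, times = solution$times,
                      period = solution$period,
                      t_peak = solution$case$waveform$t_peak)
  }
}

#' Hemodynamic index panel over the aneurysm dome
#'
#' Assembles the dome panel: average and maximum TAWSS, PWSS and OSI,
#' normalized TAWSS / PWSS, and the peak-systole and time-averaged low
#' shear areas.
#'
#' @param record a [wall_shear_record()].
#' @return a `hemodynamic_report` data.frame (`quantity`, `value`).
#' @export
hemodynamic_report <- function(record) {
  dome <- "dome"
  tawss <- compute_tawss(record)
  pwss <- compute_peak_quantities(record)$pwss
  osi <- compute_osi(record)
  a <- record$areas
  tg <- record$tags
  has_wall <- any(tg == "wall")
  nrmv <- if (has_wall) compute_normalized(record) else c(ntawss = NA, npwss = NA)
  df <- data.frame(
    quantity = c("PWSS aver (Pa)", "PWSS max (Pa)", "TAWSS aver (Pa)",
                 "TAWSS max (Pa)", "OSI aver", "OSI max", "NTAWSS (%)",
                 "NPWSS (%)", "PLSA (%)", "TALSA (%)"),
    value = c(region_average(pwss, a, tg, dome), region_max(pwss, a, tg, dome),
              region_average(tawss, a, tg, dome), region_max(tawss, a, tg, dome),
              region_average(osi, a, tg, dome), region_max(osi, a, tg, dome),
              nrmv["ntawss"], nrmv["npwss"],
              compute_lsa(record, "peak"),
              compute_lsa(record, "time_averaged")))
  class(df) <- c("hemodynamic_report", "data.frame")
  df
}

#' @export
print.hemodynamic_report <- function(x, ...) {
  disp <- x
  dec <- ifelse(grepl("OSI", x$quantity), 4, ifelse(grepl("%", x$quantity), 2, 3))
  disp$value <- mapply(round, x$value, dec)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Write an index report as CSV or JSON
#'
#' @param report a `hemodynamic_report` or any data.frame.
#' @param path output path; format chosen by extension (.csv / .json).
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.list(stats::setNames(report$value, report$quantity)),
                         path, auto_unbox = TRUE, digits = NA)
  else
    utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
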