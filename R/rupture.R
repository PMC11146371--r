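#' Rupture site specification
#'
#' A marked point on the aneurysm wall plus the radius of the sphere whose
#' intersection with the wall defines the rupture-site region (0.5 mm in
#' the reference protocol).
#'
#' @param center numeric length-3, mm.
#' @param radius sphere radius, mm (default 0.5).
#' @return a `rupture_site_spec`.
#' @export
rupture_site_spec <- function(center, radius = 0.5) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "rupture_site_spec")
}

#' Select the rupture-site region on the wall
#'
#' The marked centre is snapped to the nearest wall vertex (the measured
#' displacement is reported via `message()` and returned), then all wall or
#' dome facets whose centroid lies within the sphere are selected.
#'
#' @param mesh a `surface_mesh`.
#' @param spec a [rupture_site_spec()].
#' @return list with `facets` (indices), `area` (mm^2), `center` (snapped,
#'   mm) and `displacement` (snap distance, mm).
#' @export
select_rupture_region <- function(mesh, spec) {
  stopifnot(inherits(spec, "rupture_site_spec"))
  wallish <- which(mesh$region_tags %in% c("wall", "dome"))
  if (length(wallish) == 0) stop("mesh has no wall/dome facets")
  vid <- region_vertex_ids(mesh, c("wall", "dome"))
  dv <- sqrt(rowSums((mesh$vertices[vid, , drop = FALSE] -
                        matrix(spec$center, length(vid), 3, byrow = TRUE))^2))
  snapped <- mesh$vertices[vid[which.min(dv)], ]
  displacement <- min(dv)
  if (displacement > 1e-9)
    message(sprintf("rupture-site centre snapped to the wall by %.4f mm",
                    displacement))
  cent <- triangle_centroids(mesh)[wallish, , drop = FALSE]
  d <- sqrt(rowSums((cent - matrix(snapped, nrow(cent), 3, byrow = TRUE))^2))
  sel <- wallish[d <= spec$radius]
  if (length(sel) == 0) {
    near <- cent[which.min(d), ]
    stop(sprintf(paste0("rupture sphere (radius %.3g mm) intersects no wall ",
                        "facet; nearest wall facet centroid at (%.3f, %.3f, %.3f) mm"),
                 spec$radius, near[1], near[2], near[3]))
  }
  list(facets = sel, area = sum(triangle_areas(mesh)[sel]),
       center = snapped, displacement = displacement)
}

#' Compare rupture-site averages with dome averages
#'
#' Area-weighted averages of each supplied facet field over the dome and
#' the rupture site, with their relative percentage difference
#' `100 (site - dome) / dome`, reported to one decimal.
#'
#' @param fields named list of per-facet numeric vectors (e.g.
#'   `list(TAWSS = ..., OSI = ...)`).
#' @param areas facet areas.
#' @param dome facet indices (or logical mask) of the dome region.
#' @param site facet indices (or logical mask) of the rupture site.
#' @return a `site_comparison` data.frame with columns `quantity`, `dome`,
#'   `site`, `relative_difference`.
#' @export
compare_site_to_dome <- function(fields, areas, dome, site) {
  if (is.logical(dome)) dome <- which(dome)
  if (is.logical(site)) site <- which(site)
  if (length(dome) == 0 || length(site) == 0)
    stop("dome and rupture-site regions must both be nonempty")
  rows <- lapply(names(fields), function(nm) {
    x <- fields[[nm]]
    dv <- sum(x[dome] * areas[dome]) / sum(areas[dome])
    sv <- sum(x[site] * areas[site]) / sum(areas[site])
    rd <- if (dv == 0) NA_real_ else round(100 * (sv - dv) / dv, 1)
    data.frame(quantity = nm, dome = dv, site = sv, relative_difference = rd)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$relative_difference))
    warning("dome average is zero for some quantity; relative difference undefined")
  class(out) <- c("site_comparison", "data.frame")
  out
}

#' Classify the hemodynamic regime at the rupture site
#'
#' Rupture points fall into two characteristic environments: near a
#' recirculating vortex the site shows depressed wall shear and elevated
#' OSI (`low_wss_high_osi`); in an impinging jet the site shows elevated
#' shear and depressed OSI (`high_wss_jet`). Sites matching neither pattern
#' (such as ruptures within a bleb) are `indeterminate`.
#'
#' @param comparison a [compare_site_to_dome()] result containing `TAWSS`
#'   and `OSI` rows.
#' @param tawss_threshold,osi_threshold relative-difference thresholds in
#'   percent (defaults 25).
#' @return one of `"low_wss_high_osi"`, `"high_wss_jet"`, `"indeterminate"`.
#' @export
classify_site_regime <- function(comparison, tawss_threshold = 25,
                                 osi_threshold = 25) {
  gt <- function(nm) {
    r <- comparison$relative_difference[comparison$quantity == nm]
    if (length(r) != 1 || is.na(r))
      stop("comparison must contain a '", nm, "' row with a defined relative difference")
    r
  }
  dt <- gt("TAWSS")
  do <- gt("OSI")
  if (dt < -tawss_threshold && do > osi_threshold) "low_wss_high_osi"
  else if (dt > tawss_threshold && do < -osi_threshold) "high_wss_jet"
  else "indeterminate"
}
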