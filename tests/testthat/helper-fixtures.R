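# Shared fixtures. Expensive solver fixtures are memoised so several test
# files can reuse one solve.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

# watertight UV sphere, upper hemisphere tagged dome, lower tagged wall,
# equatorial neck plane
uv_sphere <- function(radius = 5, nlat = 24, nlon = 48, center = c(0, 0, 0)) {
  lat <- seq(-pi / 2, pi / 2, length.out = nlat + 1)[-c(1, nlat + 1)]
  lon <- 2 * pi * (seq_len(nlon) - 1) / nlon
  ring <- function(phi) cbind(radius * cos(phi) * cos(lon),
                              radius * cos(phi) * sin(lon),
                              radius * sin(phi))
  V <- rbind(c(0, 0, -radius), do.call(rbind, lapply(lat, ring)), c(0, 0, radius))
  V <- V + matrix(center, nrow(V), 3, byrow = TRUE)
  bot <- 1L
  top <- nrow(V)
  rid <- function(i) 1L + (i - 1L) * nlon + seq_len(nlon)
  tris <- NULL
  r1 <- rid(1)
  tris <- rbind(tris, cbind(bot, r1[c(2:nlon, 1)], r1))
  for (i in seq_len(length(lat) - 1)) {
    a <- rid(i); b <- rid(i + 1)
    a2 <- a[c(2:nlon, 1)]; b2 <- b[c(2:nlon, 1)]
    tris <- rbind(tris, cbind(a, a2, b2), cbind(a, b2, b))
  }
  rl <- rid(length(lat))
  tris <- rbind(tris, cbind(top, rl, rl[c(2:nlon, 1)]))
  cent_z <- (V[tris[, 1], 3] + V[tris[, 2], 3] + V[tris[, 3], 3]) / 3
  tags <- ifelse(cent_z > center[3], "dome", "wall")
  surface_mesh(V, tris, tags,
               neck_plane = list(point = center, normal = c(0, 0, 1)))
}

# steady Poiseuille verification solution (shared by solver, wss and piv
# tests); section edge 0.2 mm, coarse axial spacing (axially invariant flow)
tube_solution <- function() {
  memo("tube_solution", function() {
    vm <- tube_volume_mesh(2, 24, 0.2, 1.5)
    case <- flow_case(vm)
    sol <- solve_steady(case, compute_inlet_flux(2, 0.3))
    list(mesh = vm, sol = sol, record = extract_wss(sol),
         tav = 0.3, radius = 2)
  })
}

# x coordinate of wall-record facet centroids of a tube solution
tube_wall_x <- function(fix) {
  vm <- fix$mesh
  fb <- vm$boundary$faces
  cx <- (vm$vertices[fb[, 1], 1] + vm$vertices[fb[, 2], 1] +
           vm$vertices[fb[, 3], 1]) / 3
  cx[fix$sol$noslip_faces]
}

default_aneurysm <- function() {
  memo("default_aneurysm", function() build_idealized_aneurysm(aneurysm_config()))
}
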