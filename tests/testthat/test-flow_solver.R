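# Verification of the finite-element solver against the Poiseuille closed
# form and its discrete conservation / convergence properties. The shared
# tube fixture (R = 2 mm, L = 24 mm, section edge 0.2 mm) is solved once in
# helper-fixtures.R.

test_that("steady tube flow matches the Poiseuille closed form", {
  fix <- tube_solution()
  sol <- fix$sol
  mu <- 3.5e-3
  # wall WSS magnitude ~ 4 mu V / R away from the caps (5%)
  taw <- compute_tawss(fix$record)
  interior <- tube_wall_x(fix) > 6 & tube_wall_x(fix) < 18
  wss_ref <- 4 * mu * fix$tav / (fix$radius * 1e-3)
  expect_equal(mean(taw[interior]), wss_ref, tolerance = 0.05)
  # centreline velocity ~ 2 V (5%)
  f <- velocity_field(sol)
  ucl <- f(matrix(c(12, 0, 0), 1))
  expect_equal(ucl[1], 2 * fix$tav, tolerance = 0.05)
  expect_lt(abs(ucl[2]) + abs(ucl[3]), 0.02 * fix$tav)
  # velocity profile across the section: L2 error below 5%
  z <- seq(-1.8, 1.8, length.out = 41)
  pts <- cbind(12, 0, z)
  uz <- f(pts)[, 1]
  exact <- 2 * fix$tav * (1 - (z / fix$radius)^2)
  expect_lt(sqrt(mean((uz - exact)^2)) / sqrt(mean(exact^2)), 0.05)
  # pressure drop ~ 8 mu V L / R^2 (5%)
  dp_exact <- 8 * mu * fix$tav * 0.024 / (2e-3)^2
  inlet_nodes <- unique(as.vector(
    fix$mesh$boundary$faces[fix$mesh$boundary$tags == "inlet", ]))
  outlet_nodes <- unique(as.vector(
    fix$mesh$boundary$faces[fix$mesh$boundary$tags == "outlet_1", ]))
  dp <- mean(sol$p[inlet_nodes]) - mean(sol$p[outlet_nodes])
  expect_equal(dp, dp_exact, tolerance = 0.05)
})

test_that("recovered wall shear vectors are tangent and flow-aligned", {
  fix <- tube_solution()
  rec <- fix$record
  nrm <- boundary_face_normals(fix$mesh)[fix$sol$noslip_faces, , drop = FALSE]
  dotn <- abs(rowSums(rec$wss[, , 1] * nrm))
  mag <- sqrt(rowSums(rec$wss[, , 1]^2))
  expect_lt(max(dotn / pmax(mag, 1e-30)), 1e-10)
  interior <- tube_wall_x(fix) > 6 & tube_wall_x(fix) < 18
  # shear exerted by the fluid on the wall points downstream (+x)
  expect_true(all(rec$wss[interior, 1, 1] > 0))
})

test_that("global mass is conserved to round-off in steady solves", {
  fix <- tube_solution()
  fl <- boundary_flux(fix$sol)
  qin <- -fl$flux_m3_s[fl$tag == "inlet"]
  expect_equal(fl$flux_m3_s[fl$tag == "outlet_1"], qin, tolerance = 1e-10)
  expect_lt(abs(fl$flux_m3_s[fl$tag == "net"]) / qin, 1e-10)
  # imposed flux honoured
  expect_equal(qin * 6e7, fix$sol$flux_ml_min, tolerance = 1e-9)
})

test_that("zero flux yields the null solution", {
  vm <- tube_volume_mesh(2, 24, 0.5, 3)
  sol <- solve_steady(flow_case(vm), 0)
  expect_lt(max(abs(sol$u)), 1e-12)
  expect_lt(diff(range(sol$p)), 1e-8)
})

test_that("solver is deterministic", {
  vm <- tube_volume_mesh(1.5, 18, 0.45, 2)
  s1 <- solve_steady(flow_case(vm), 100)
  s2 <- solve_steady(flow_case(vm), 100)
  expect_identical(s1$u, s2$u)
  expect_identical(s1$p, s2$p)
})

test_that("pulsatile flow with a constant waveform relaxes to the steady solution", {
  vm <- tube_volume_mesh(2, 24, 0.45, 2.2)
  wfc <- make_waveform(0.3, 0.3, 0.3, 60)
  case <- flow_case(vm, waveform = wfc, dt = 1 / 50, n_cycles = 2)
  puls <- solve_pulsatile(case)
  steady <- solve_steady(flow_case(vm), compute_inlet_flux(2, 0.3))
  ulast <- puls$u_steps[[length(puls$u_steps)]]
  expect_lt(max(abs(ulast - steady$u)) / max(abs(steady$u)), 0.01)
})

test_that("pulsatile runs conserve mass, hit the systolic flux and stay periodic", {
  vm <- tube_volume_mesh(2, 24, 0.5, 2.5)
  case <- flow_case(vm, dt = 1 / 60, n_cycles = 3)
  sol <- solve_pulsatile(case)
  wf <- case$waveform
  rin <- hemoflow:::inlet_geometry(vm)$radius * 1e-3
  for (k in seq_along(sol$times)) {
    fl <- boundary_flux(sol, k)
    qin <- -fl$flux_m3_s[fl$tag == "inlet"]
    expect_lt(abs(fl$flux_m3_s[fl$tag == "net"]) / qin, 1e-3)
    # the imposed inlet flux follows the waveform exactly
    expect_equal(qin, wf$fun(sol$times[k]) * pi * rin^2, tolerance = 1e-9)
  }
  k_peak <- which.min(abs(sol$times - wf$t_peak))
  fl <- boundary_flux(sol, k_peak)
  expect_equal(-fl$flux_m3_s[fl$tag == "inlet"], wf$psv * pi * rin^2,
               tolerance = 0.01)
  # kinetic energy of the final cycle repeats the previous (post-washout)
  # cycle within 2%
  ke <- sol$kinetic_energy
  n <- length(ke) / 3
  expect_lt(max(abs(ke[(2 * n + 1):(3 * n)] - ke[(n + 1):(2 * n)]) / max(ke)),
            0.02)
})

test_that("halving the time step barely changes the final cycle", {
  vm <- tube_volume_mesh(1.6, 20, 0.55, 2.5)
  c1 <- flow_case(vm, dt = 1 / 40, n_cycles = 2)
  c2 <- flow_case(vm, dt = 1 / 80, n_cycles = 2)
  s1 <- solve_pulsatile(c1)
  s2 <- solve_pulsatile(c2)
  u1 <- s1$u_steps[[length(s1$u_steps)]]
  u2 <- s2$u_steps[[length(s2$u_steps)]]
  expect_lt(max(abs(u1 - u2)) / max(abs(u2)), 0.01)
})
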