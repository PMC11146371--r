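test_that("pathlines through closed-form fields match their analytic solutions", {
  # uniform field: 0.1 m/s along x for 10 ms -> 1 mm straight segment
  uni <- velocity_field(function(p) cbind(rep(0.1, nrow(p)), 0, 0))
  seeds <- rbind(c(0, 0, 0), c(1, 2, 3))
  ps <- trace_pathlines(uni, seeds = seeds, exposure = 0.010)
  for (i in 1:2) {
    tr <- ps$traces[[i]]
    endpoint <- tr[nrow(tr), ]
    expected <- seeds[i, ] + c(1, 0, 0)
    expect_lt(sqrt(sum((endpoint - expected)^2)) / sqrt(sum(expected^2 + 1e-30)),
              1e-6)
    # straight: all points on the seed's line
    expect_lt(max(abs(tr[, 2] - seeds[i, 2])), 1e-9)
  }

  # rigid rotation about z, omega = 50 rad/s: circular arc of 0.5 rad
  omega <- 50
  rot <- velocity_field(function(p)
    cbind(-omega * p[, 2], omega * p[, 1], 0) / 1000)  # mm/s -> m/s units
  seeds <- rbind(c(2, 0, 0), c(0, 3, 1))
  ps <- trace_pathlines(rot, seeds = seeds, exposure = 0.010)
  for (i in 1:2) {
    tr <- ps$traces[[i]]
    th <- omega * 0.010
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    expected <- as.numeric(R %*% seeds[i, ])
    err <- sqrt(sum((tr[nrow(tr), ] - expected)^2)) / sqrt(sum(expected^2))
    expect_lt(err, 1e-6)
    # radius conservation along the whole trace
    r0 <- sqrt(sum(seeds[i, 1:2]^2))
    expect_lt(max(abs(sqrt(tr[, 1]^2 + tr[, 2]^2) - r0)) / r0, 1e-6)
  }

  # zero field: zero-length traces
  zero <- velocity_field(function(p) matrix(0, nrow(p), 3))
  ps0 <- trace_pathlines(zero, seeds = rbind(c(1, 1, 1)), exposure = 0.010)
  expect_lt(max(dist(ps0$traces[[1]])), 1e-12)
})

test_that("random dome seeding is reproducible and stays inside the lumen", {
  fix <- tube_solution()
  sol <- fix$sol
  sol$mesh$neck_plane <- NULL
  a <- trace_pathlines(sol, n_seeds = 25, seed = 9)
  b <- trace_pathlines(sol, n_seeds = 25, seed = 9)
  expect_identical(a$seeds, b$seeds)
  f <- velocity_field(sol)
  expect_false(anyNA(f(a$seeds)))
})

test_that("focal band filtering keeps mid-plane traces and is monotone in DOF", {
  uni <- velocity_field(function(p) cbind(rep(0.05, nrow(p)), 0, 0))
  set.seed(2)
  seeds <- cbind(runif(60, 0, 5), runif(60, 0, 5), runif(60, -0.5, 0.5))
  ps <- trace_pathlines(uni, seeds = seeds, exposure = 0.010)
  plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  huge <- render_focal_band(ps, plane, dof = 1e7)
  expect_length(huge$traces, 60)
  expect_true(all(huge$depth_code >= 0 & huge$depth_code <= 1))
  # a trace lying exactly in the plane has depth code zero
  on_plane <- trace_pathlines(uni, seeds = rbind(c(1, 1, 0)), exposure = 0.01)
  expect_equal(render_focal_band(on_plane, plane, 248)$depth_code, 0)
  counts <- vapply(c(2000, 1000, 500, 250), function(dof)
    length(render_focal_band(ps, plane, dof)$traces), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # the whole-trace rule is at least as strict as the midpoint rule
  expect_lte(length(render_focal_band(ps, plane, 500, rule = "whole")$traces),
             length(render_focal_band(ps, plane, 500)$traces))
})

test_that("line probes through a Poiseuille tube recover the parabolic profile", {
  fix <- tube_solution()
  probe <- line_probe(p1 = c(12, 0, 1.9), p2 = c(12, 0, -1.9),
                      plane_point = c(12, 0, 0), plane_normal = c(0, 1, 0),
                      dof = 248)
  prof <- sample_velocity_line(fix$sol, probe, n_points = 81)
  mid <- prof[prof$band == "mid", ]
  vmax <- max(mid$velocity_m_s, na.rm = TRUE)
  expect_equal(vmax, 2 * fix$tav, tolerance = 0.05)
  # near-wall samples approach zero
  ends <- mid$velocity_m_s[c(1, nrow(mid))]
  expect_true(all(ends < 0.25 * vmax))
  # the analytic parabola matches along the line (5%)
  z <- seq(1.9, -1.9, length.out = 81)
  expect_lt(max(abs(mid$velocity_m_s - 2 * fix$tav * (1 - (z / 2)^2))) /
              (2 * fix$tav), 0.05)
  # reversal symmetry
  rev_probe <- line_probe(c(12, 0, -1.9), c(12, 0, 1.9),
                          plane_point = c(12, 0, 0),
                          plane_normal = c(0, 1, 0))
  prof_r <- sample_velocity_line(fix$sol, rev_probe, n_points = 81)
  expect_equal(rev(prof_r$velocity_m_s[prof_r$band == "mid"]),
               mid$velocity_m_s, tolerance = 1e-10)
  # degenerate shift: dof = 0 collapses the three bands
  p0 <- line_probe(c(12, 0, 1.9), c(12, 0, -1.9), c(12, 0, 0), c(0, 1, 0),
                   dof = 1e-9)
  prof0 <- sample_velocity_line(fix$sol, p0, n_points = 21)
  expect_equal(prof0$velocity_m_s[prof0$band == "upper"],
               prof0$velocity_m_s[prof0$band == "mid"], tolerance = 1e-6)
  expect_error(
    sample_velocity_line(fix$sol,
                         line_probe(c(100, 100, 0), c(101, 100, 0),
                                    c(0, 0, 0), c(0, 0, 1))),
    "outside the lumen")
})

test_that("kinematic similarity matches blood against the circulating medium", {
  blood <- fluid_properties(3.5e-3, 1050)
  medium <- fluid_properties(3.75e-3, 1125)
  res <- check_kinematic_similarity(blood, medium)
  expect_equal(res$ratio_a, 3e5)
  expect_equal(res$ratio_b, 3e5)
  expect_true(res$similar)
  expect_true(check_kinematic_similarity(blood, blood)$similar)
  water <- fluid_properties(1.0e-3, 1000)
  expect_false(check_kinematic_similarity(water, blood)$similar)
})
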