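test_that("idealized aneurysm surfaces are watertight with a clean tag partition", {
  configs <- list(
    aneurysm_config(),
    aneurysm_config(dome_radius = 5.5, neck_radius = 3.5, parent_radius = 1.8,
                    parent_length = 24, mesh_edge_length = 0.45),
    aneurysm_config(bleb = list(radius = 1.2, direction = c(0.4, 0.3, 0.9)),
                    mesh_edge_length = 0.45, seed = 7))
  for (cfg in configs) {
    surf <- build_idealized_aneurysm(cfg)
    expect_true(mesh_is_watertight(surf))
    expect_gt(enclosed_volume(surf), 0)
    expect_setequal(unique(surf$region_tags),
                    c("wall", "dome", "inlet", "outlet_1"))
    # tags partition the surface: per-tag areas sum to the total area
    expect_equal(sum(region_areas(surf)), sum(triangle_areas(surf)))
    expect_false(is.null(surf$neck_plane))
  }
})

test_that("sidewall layout has exactly one inlet and one outlet", {
  surf <- default_aneurysm()
  expect_gt(sum(surf$region_tags == "inlet"), 0)
  expect_gt(sum(surf$region_tags == "outlet_1"), 0)
  expect_length(grep("^outlet", unique(surf$region_tags)), 1)
  # caps are exactly planar lattice sections
  for (tag in c("inlet", "outlet_1")) {
    vid <- unique(as.vector(surf$triangles[surf$region_tags == tag, ]))
    expect_lt(diff(range(surf$vertices[vid, 1])), 1e-9)
  }
})

test_that("bifurcation layout carries two outlets and a flow-divider dome", {
  surf <- build_idealized_aneurysm(
    aneurysm_config(bifurcation = TRUE, parent_length = 26,
                    mesh_edge_length = 0.5))
  expect_true(mesh_is_watertight(surf))
  expect_setequal(grep("^outlet", unique(surf$region_tags), value = TRUE),
                  c("outlet_1", "outlet_2"))
  expect_gt(sum(surf$region_tags == "dome"), 0)
})

test_that("dome-tagged area matches the spherical-cap closed form", {
  cfg <- aneurysm_config(dome_radius = 5, neck_radius = 2.5, parent_radius = 2,
                         mesh_edge_length = 0.2)
  surf <- build_idealized_aneurysm(cfg)
  zc <- cfg$dome_offset
  zn <- zc - sqrt(5^2 - 2.5^2)
  cap_area <- 2 * pi * 5 * (5 + (zc - zn))  # sphere area minus the neck cap
  got <- sum(triangle_areas(surf)[surf$region_tags == "dome"])
  expect_lt(abs(got - cap_area) / cap_area, 0.02)
})

test_that("invalid aneurysm configurations are rejected with diagnostics", {
  expect_error(aneurysm_config(dome_radius = 5, neck_radius = 5),
               "neck_radius")
  expect_error(aneurysm_config(parent_length = 10), "six-diameter")
  # dome reaching past the openings is a self-intersecting configuration
  expect_error(build_idealized_aneurysm(
    aneurysm_config(parent_length = 24, dome_radius = 11.5,
                    neck_radius = 3, dome_offset = 3)),
    "dome")
})

test_that("straight tube surface matches cylinder geometry", {
  surf <- build_straight_tube(2, 48, 0.2)
  expect_true(mesh_is_watertight(surf))
  wall_area <- sum(triangle_areas(surf)[surf$region_tags == "wall"])
  expect_lt(abs(wall_area - 2 * pi * 2 * 48) / (2 * pi * 2 * 48), 0.01)
  expect_setequal(unique(surf$region_tags), c("wall", "inlet", "outlet_1"))
  # outward orientation: positive enclosed volume close to pi R^2 L
  expect_lt(abs(enclosed_volume(surf) - pi * 4 * 48) / (pi * 4 * 48), 0.01)
  expect_error(build_straight_tube(2, 10, 0.2), "12 x radius")
  expect_error(build_straight_tube(-1, 48, 0.2), "positive")
})

test_that("wall-field fixtures deliver their stated construction", {
  plate <- build_flat_plate(20, 20, 10, 10)  # 800 equal-area facets
  fix <- synth_wall_field(plate, wall_field_config(low_shear_fraction = 0.15,
                                                   magnitude_jitter = 0))
  expect_equal(fix$truth$low_area_fraction, 0.15)
  expect_equal(compute_lsa(fix$record, "peak", reference = "dome"), 15)

  fix0 <- synth_wall_field(plate, wall_field_config(reversing_fraction = 0))
  expect_true(all(fix0$truth$osi == 0))
  fix1 <- synth_wall_field(plate, wall_field_config(reversing_fraction = 1,
                                                    n_steps = 20))
  expect_true(all(fix1$truth$osi == 0.5))
  expect_equal(fix1$truth$reversing_area_fraction, 1)
})

test_that("fixture construction is deterministic in the seed", {
  plate <- build_flat_plate(10, 10)
  a <- synth_wall_field(plate, wall_field_config(seed = 42))
  b <- synth_wall_field(plate, wall_field_config(seed = 42))
  expect_identical(a$record$wss, b$record$wss)
  c2 <- synth_wall_field(plate, wall_field_config(seed = 43))
  expect_false(identical(a$record$wss, c2$record$wss))
})
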