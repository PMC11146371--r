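test_that("sphere intersection with a flat plate recovers the disc area", {
  plate <- build_flat_plate(200, 200, 10, 10)  # edge 0.05 mm
  spec <- rupture_site_spec(c(5, 5, 0), radius = 0.5)
  reg <- select_rupture_region(plate, spec)
  expect_lt(abs(reg$area - pi * 0.25) / (pi * 0.25), 0.10)
  reg2 <- select_rupture_region(plate, rupture_site_spec(c(5, 5, 0), 1.0))
  expect_equal(reg2$area / reg$area, 4, tolerance = 0.1)
})

test_that("degenerate spheres and off-wall centres are handled", {
  plate <- build_flat_plate(4, 4, 10, 10)  # facet size >> radius
  expect_error(select_rupture_region(plate, rupture_site_spec(c(5, 5, 0), 0.01)),
               "nearest wall")
  # off-wall centre is snapped and reported
  plate2 <- build_flat_plate(40, 40, 10, 10)
  expect_message(
    reg <- select_rupture_region(plate2, rupture_site_spec(c(5, 5, 2), 0.6)),
    "snapped")
  expect_gt(reg$displacement, 1.9)
  expect_gt(length(reg$facets), 0)
})

test_that("site/dome comparison reproduces the printed relative differences", {
  # two uniform regions carrying the printed dome and site averages
  make_cmp <- function(dome_tawss, site_tawss, dome_osi, site_osi) {
    fields <- list(TAWSS = c(dome_tawss, site_tawss),
                   OSI = c(dome_osi, site_osi))
    compare_site_to_dome(fields, areas = c(1, 1), dome = 1, site = 2)
  }
  cmpA <- make_cmp(2.764, 1.022, 0.0082, 0.0163)
  expect_equal(cmpA$relative_difference[cmpA$quantity == "TAWSS"], -63.0)
  expect_equal(cmpA$relative_difference[cmpA$quantity == "OSI"], 98.8)
  cmpC <- make_cmp(0.776, 0.2, 0.0144, 0.0526)
  expect_equal(cmpC$relative_difference[cmpC$quantity == "OSI"], 265.3)
  cmpE <- make_cmp(1.056, 2.861, 0.0143, 0.004)
  expect_equal(cmpE$relative_difference[cmpE$quantity == "TAWSS"], 170.9)
  expect_equal(cmpE$relative_difference[cmpE$quantity == "OSI"], -72.0)
})

test_that("identical fields give zero relative difference; zero dome flags NA", {
  fields <- list(TAWSS = c(2, 2, 2))
  cmp <- compare_site_to_dome(fields, areas = rep(1, 3), dome = 1:3, site = 2)
  expect_equal(cmp$relative_difference, 0)
  expect_warning(
    cmp0 <- compare_site_to_dome(list(OSI = c(0, 1)), c(1, 1), 1, 2),
    "zero")
  expect_true(is.na(cmp0$relative_difference))
})

test_that("regime classification separates vortex, jet and bleb patterns", {
  mk <- function(dt, do.) {
    data.frame(quantity = c("TAWSS", "OSI"), dome = c(1, 0.01),
               site = c(1, 0.01), relative_difference = c(dt, do.))
  }
  expect_equal(classify_site_regime(mk(-63.0, 98.8)), "low_wss_high_osi")
  expect_equal(classify_site_regime(mk(170.9, -72.0)), "high_wss_jet")
  expect_equal(classify_site_regime(mk(0, 0)), "indeterminate")
  expect_equal(classify_site_regime(mk(-98.0, -51.2)), "indeterminate")
})

test_that("classification is invariant to uniform rescaling of both fields", {
  plate <- build_flat_plate(20, 20)
  fix <- synth_wall_field(plate, wall_field_config(low_shear_fraction = 0.1,
                                                   reversing_fraction = 0.3))
  rec <- fix$record
  tawss <- compute_tawss(rec)
  osi <- compute_osi(rec)
  site <- which(rec$tags == "dome")[1:20]
  dome <- seq_along(rec$tags)
  c1 <- compare_site_to_dome(list(TAWSS = tawss, OSI = osi), rec$areas, dome, site)
  c2 <- compare_site_to_dome(list(TAWSS = 7 * tawss, OSI = 7 * osi),
                             rec$areas, dome, site)
  expect_equal(classify_site_regime(c1), classify_site_regime(c2))
  expect_equal(c1$relative_difference, c2$relative_difference)
})
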