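# fixture-based verification of every index kernel against the generator's
# closed-form ground truth, plus the analytic invariants of OSI and LSA

fixture_meshes <- function() {
  list(plate = build_flat_plate(12, 12),
       aneurysm = default_aneurysm())
}

test_that("index kernels reproduce fixture ground truth to round-off", {
  cfgs <- list(
    wall_field_config(),
    wall_field_config(low_shear_fraction = 0.15, reversing_fraction = 0.3),
    wall_field_config(low_shear_fraction = 0.4, reversing_fraction = 1,
                      n_steps = 16, base_magnitude = 5.5),
    wall_field_config(reversing_fraction = 0.7, n_steps = 9, seed = 3))
  for (mesh in fixture_meshes()) {
    for (cfg in cfgs) {
      fix <- synth_wall_field(mesh, cfg)
      rec <- fix$record
      expect_equal(compute_tawss(rec), fix$truth$tawss, tolerance = 1e-12)
      expect_equal(compute_osi(rec), fix$truth$osi, tolerance = 1e-12)
      expect_equal(compute_peak_quantities(rec)$pwss, fix$truth$pwss,
                   tolerance = 1e-12)
      expect_equal(compute_lsa(rec, "peak"), fix$truth$plsa, tolerance = 1e-10)
      expect_equal(compute_lsa(rec, "time_averaged"), fix$truth$talsa,
                   tolerance = 1e-10)
      if (!is.na(fix$truth$ntawss)) {
        nv <- compute_normalized(rec)
        expect_equal(unname(nv["ntawss"]), fix$truth$ntawss, tolerance = 1e-10)
        expect_equal(unname(nv["npwss"]), fix$truth$npwss, tolerance = 1e-10)
      }
    }
  }
})

test_that("OSI is bounded, zero for steady fields, 0.5 for reversal", {
  plate <- build_flat_plate(10, 10)
  set.seed(5)
  for (i in 1:5) {
    cfg <- wall_field_config(reversing_fraction = runif(1), n_steps = 12,
                             seed = i)
    rec <- synth_wall_field(plate, cfg)$record
    osi <- compute_osi(rec)
    expect_true(all(osi >= 0 & osi <= 0.5))
  }
  steady <- synth_wall_field(plate, wall_field_config(reversing_fraction = 0))
  expect_lt(max(compute_osi(steady$record)), 1e-12)
  flip <- synth_wall_field(plate, wall_field_config(reversing_fraction = 1,
                                                    n_steps = 8))
  expect_lt(max(abs(compute_osi(flip$record) - 0.5)), 1e-12)
})

test_that("temporal quadrature handles piecewise-constant magnitudes", {
  # one facet, |wss| = a over the first half-period and b over the second
  a <- 3; b <- 1
  nt <- 10
  wss <- array(0, c(1, 3, nt))
  wss[1, 1, ] <- c(rep(a, nt / 2), rep(b, nt / 2))
  rec <- wall_shear_record(wss, areas = 1, tags = "dome",
                           times = (0:(nt - 1)) / nt, period = 1)
  expect_equal(compute_tawss(rec), (a + b) / 2)
  # constant field: PWSS equals TAWSS
  wss[1, 1, ] <- 2
  rec2 <- wall_shear_record(wss, 1, "dome", (0:(nt - 1)) / nt, 1)
  expect_equal(compute_peak_quantities(rec2)$pwss, compute_tawss(rec2))
})

test_that("PWSS over TAWSS follows the waveform PSV over TAV ratio", {
  wf <- make_waveform(0.45, 0.2, 0.3, 60)
  nt <- 40
  times <- (0:(nt - 1)) / nt
  w <- wf$fun(times)
  nf <- 6
  wss <- array(0, c(nf, 3, nt))
  for (k in seq_len(nt)) wss[, 1, k] <- 2 * w[k]  # shear follows the waveform
  rec <- wall_shear_record(wss, rep(1, nf), rep("dome", nf), times, 1,
                           t_peak = wf$t_peak)
  ratio <- compute_peak_quantities(rec)$pwss[1] / compute_tawss(rec)[1]
  expect_equal(ratio, wf$psv / mean(w), tolerance = 1e-6)
  expect_equal(ratio, 1.5, tolerance = 0.02)  # PSV/TAV at the study values
})

test_that("LSA is zero for uniform fields and non-increasing under dome scaling", {
  plate <- build_flat_plate(10, 10)
  uni <- synth_wall_field(plate, wall_field_config(magnitude_jitter = 0))
  expect_equal(compute_lsa(uni$record, "peak"), 0)
  fix <- synth_wall_field(plate, wall_field_config(low_shear_fraction = 0.2))
  rec <- fix$record
  lsa0 <- compute_lsa(rec, "peak", reference = "dome")
  # scale every dome shear up with the reference fixed: recompute with a
  # fixed threshold by scaling both, reference from the unscaled record
  prev <- lsa0
  for (s in c(2, 5, 20)) {
    rec2 <- rec
    rec2$wss <- rec$wss * s
    m <- sqrt(rec2$wss[, 1, ]^2 + rec2$wss[, 2, ]^2 + rec2$wss[, 3, ]^2)
    thr <- 0.1 * sum(sqrt(rec$wss[, 1, 1]^2 + rec$wss[, 2, 1]^2 +
                            rec$wss[, 3, 1]^2) * rec$areas) / sum(rec$areas)
    lsa_s <- 100 * sum(rec$areas[m[, 1] < thr]) / sum(rec$areas)
    expect_lte(lsa_s, prev + 1e-12)
    prev <- lsa_s
  }
  # peak and cycle-integrated LSA agree for time-invariant fields
  expect_equal(compute_lsa(rec, "peak"), compute_lsa(rec, "time_averaged"))
})

test_that("region averages are area-weighted and dominated by the maximum", {
  areas <- c(1, 1)
  expect_equal(region_average(c(1, 3), areas, c("dome", "dome"), "dome"), 2)
  expect_equal(region_average(c(1, 3), c(1, 3), c("dome", "dome"), "dome"), 2.5)
  expect_equal(region_average(c(4, 4), areas, c("dome", "dome"), "dome"), 4)
  expect_equal(region_max(c(1, 3), areas, c("dome", "dome"), "dome"), 3)
  expect_error(region_average(1, 1, "dome", "wall"), "empty")
})

test_that("the dome panel satisfies its structural invariants", {
  fix <- synth_wall_field(default_aneurysm(),
                          wall_field_config(low_shear_fraction = 0.1,
                                            reversing_fraction = 0.25))
  panel <- hemodynamic_report(fix$record)
  val <- function(q) panel$value[panel$quantity == q]
  expect_gte(val("TAWSS max (Pa)"), val("TAWSS aver (Pa)"))
  expect_gte(val("PWSS max (Pa)"), val("PWSS aver (Pa)"))
  expect_gte(val("OSI max"), val("OSI aver"))
  expect_true(val("OSI aver") >= 0 && val("OSI max") <= 0.5)
  pct <- panel$value[grepl("%", panel$quantity)]
  expect_true(all(pct >= 0))
  expect_true(all(panel$value[grepl("LSA", panel$quantity)] <= 100))
})
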