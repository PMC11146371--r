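test_that("waveform satisfies its PSV/EDV/TAV constraints", {
  wf <- make_waveform(0.45, 0.2, 0.3, 60)
  expect_equal(wf$period, 1)
  t <- seq(0, 1, length.out = 4001)
  w <- wf$fun(t)
  expect_equal(max(w), 0.45, tolerance = 1e-3)
  expect_equal(min(w), 0.2, tolerance = 1e-3)
  mean_w <- (sum(w) - (w[1] + w[4001]) / 2) / 4000  # trapezoid oracle
  expect_equal(mean_w, 0.3, tolerance = 1e-3)
  # periodicity and positivity
  expect_equal(wf$fun(t), wf$fun(t + 3), tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_equal(wf$fun(wf$t_peak), 0.45, tolerance = 1e-6)
})

test_that("waveform handles degenerate and general triples", {
  wfc <- make_waveform(0.3, 0.3, 0.3, 60)
  expect_equal(wfc$fun(seq(0, 1, 0.01)), rep(0.3, 101))
  # property sweep: random feasible triples, including means above midpoint
  set.seed(11)
  for (i in 1:20) {
    edv <- runif(1, 0.05, 0.3)
    psv <- edv + runif(1, 0.05, 0.4)
    tav <- runif(1, edv + 0.01 * (psv - edv), psv - 0.01 * (psv - edv))
    wf <- make_waveform(psv, edv, tav, heart_rate = sample(c(50, 60, 75), 1))
    t <- wf$period * seq(0, 1, length.out = 2001)
    w <- wf$fun(t)
    expect_equal(max(w), psv, tolerance = 2e-3)
    expect_equal(min(w), edv, tolerance = 2e-3)
    expect_equal(mean(w[-1]), tav, tolerance = 1e-3 * tav + 1e-4)
  }
  expect_error(make_waveform(0.3, 0.2, 0.5, 60), "infeasible")
  expect_error(make_waveform(0.3, 0.35, 0.3, 60), "infeasible")
})

test_that("sampled waveforms override the analytic shape", {
  tt <- seq(0, 0.95, by = 0.05)
  vv <- 0.3 + 0.1 * sin(2 * pi * tt)
  wf <- make_waveform(psv = max(vv), edv = min(vv), tav = 0.3,
                      samples = cbind(tt, vv))
  expect_equal(wf$fun(tt), vv)
})

test_that("inlet flux table reproduces the printed radius/flux pairs", {
  radii <- c(A = 2.089, B = 2.194, C = 1.909, D = 2.153, E = 1.924)
  printed <- c(A = 247, B = 272, C = 206, D = 262, E = 209)
  for (nm in names(radii))
    expect_equal(compute_inlet_flux(radii[[nm]], 0.3), printed[[nm]])
  expect_equal(compute_inlet_flux(2, 0), 0)
})

test_that("mean velocity from flux matches the printed PIV parameters", {
  expect_equal(tav_from_flux(2.194, 169), 0.19)
  expect_equal(tav_from_flux(1.909, 169), 0.25)
  # round trip within the table's rounding
  for (r in c(1.6, 1.909, 2.194, 2.5))
    expect_equal(tav_from_flux(r, compute_inlet_flux(r, 0.27)), 0.27,
                 tolerance = 0.01)
})
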