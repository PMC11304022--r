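props <- thermal_properties()

test_that("thermal properties carry the published constants", {
  expect_identical(props$rho, 1050)
  expect_identical(props$C, 4219)
  expect_identical(props$kt, 0.7)
  expect_equal(props$kappa, 0.7 / (1050 * 4219))
  expect_error(thermal_properties(kt = -1), "")
})

test_that("a uniform body-temperature field with no spots is invariant", {
  f <- temperature_field(c(15, 15, 5))
  f2 <- run_heat(f, props, list(), duration = 5)
  expect_equal(f2$T, f$T, tolerance = 1e-12)
})

test_that("the steady profile between fixed-temperature faces is linear", {
  fx <- generate_fixtures("small-heat-slab", n = 9)
  ss <- steady_state_heat(fx$field, props, list(fx$spot), tol = 1e-5)
  # a full-width spot makes the slab effectively 1D: linear 5 -> 37 column
  ic <- fx$center_index
  expect_equal(ss$T[ic, ], rev(fx$truth$steady), tolerance = 0.1)
})

test_that("the discrete maximum principle bounds every step", {
  f <- temperature_field(c(21, 21, 5), spacing = c(0.03, 0.03, 0.03))
  sp <- cold_spot(c(0.3, 0.3), radius = 0.15, T_spot = 5)
  cur <- f
  for (k in 1:5) {
    cur <- run_heat(cur, props, list(sp), duration = 2)
    expect_gte(min(cur$T), 5 - 1e-9)
    expect_lte(max(cur$T), 37 + 1e-9)
  }
})

test_that("an arbitrary field relaxes to uniform body temperature", {
  f <- temperature_field(c(11, 11, 4))
  set.seed(42)
  f$T[] <- runif(length(f$T), 10, 37)
  ss <- steady_state_heat(f, props, list(), tol = 1e-5)
  expect_equal(max(abs(ss$T - 37)), 0, tolerance = 0.05)
})

test_that("dt above the heat stability bound is rejected with the bound", {
  f <- temperature_field(c(11, 11, 4))
  dmax <- heat_dt_max(f, props)
  expect_error(run_heat(f, props, list(), 1, dt_heat = 2 * dmax),
               "stability bound")
})

test_that("transmural establishment time scales with thickness squared", {
  sp <- cold_spot(c(0.9, 0.9), radius = 0.45, T_spot = 5)
  t1 <- transmural_establishment_time(props, sp, thickness = 0.1,
                                      lateral = 1.8, resolution = 0.05)
  t2 <- transmural_establishment_time(props, sp, thickness = 0.2,
                                      lateral = 1.8, resolution = 0.05)
  expect_gt(t2, t1)  # strictly longer through a thicker wall
  # diffusive L^2 scaling within 15% when the spot is wide against the wall
  expect_equal(as.numeric(t2) / as.numeric(t1), 4, tolerance = 0.15)
})

test_that("moving the spot deactivates the old column and grows a new one", {
  f <- temperature_field(c(31, 31, 4), spacing = c(0.03, 0.03, 0.03))
  sp0 <- list(cold_spot(c(0.3, 0.45), radius = 0.15, T_spot = 5))
  f1 <- run_heat(f, props, sp0, duration = 6)
  old_col <- f1$T[11, 16, 3]
  expect_lt(old_col, 30)  # cooled under the first spot
  spots <- move_spot(sp0, c(0.6, 0.45), t = 6)
  expect_identical(spots[[1]]$t_off, 6)
  expect_identical(spots[[2]]$t_on, 6)
  f2 <- run_heat(f1, props, spots, duration = 10, t0 = 6)
  # old footprint rewarmed toward 37, new column colder than before
  expect_gt(f2$T[11, 16, 3], old_col + 2)
  expect_lt(f2$T[21, 16, 3], 25)
  # moving outside the domain is rejected
  expect_error(move_spot(spots, c(5, 5), 16, domain = c(0.9, 0.9)),
               "outside")
  # mirror symmetry: centered spot keeps the field symmetric
  fs <- temperature_field(c(21, 21, 4))
  spc <- cold_spot(c(0.3, 0.3), radius = 0.12, T_spot = 5)
  f3 <- run_heat(fs, props, list(spc), duration = 4)
  expect_equal(f3$T, f3$T[21:1, , ], tolerance = 1e-9)
})
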