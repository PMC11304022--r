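test_that("ap_metrics matches closed forms on the ramp fixture", {
  fx <- generate_fixtures("synthetic-ap-trace", seed = 7)
  m <- ap_metrics(fx$trace, stim_times = 9.5)
  expect_true(m$captured)
  expect_equal(unname(m$RMP), -80)
  expect_equal(unname(m$peak), 20)
  # linear 1 mV/ms fall: APD_X = X ms (measured from the instant upstroke)
  expect_equal(unname(m$apd[["APD90"]]), 90, tolerance = 0.02)
  expect_equal(unname(m$apd[["APD50"]]), 50, tolerance = 0.02)
  expect_equal(unname(m$apd[["APD40"]]), 40, tolerance = 0.02)
})

test_that("ap_metrics reports no capture instead of NaN", {
  flat <- data.frame(t = seq(0, 200, 0.5), V = -80)
  m <- ap_metrics(flat, stim_times = 10)
  expect_false(m$captured)
  expect_true(all(is.na(m$apd)))
})

test_that("current_ratio preserves sign and rejects a zero baseline", {
  expect_identical(current_ratio(5, 5), 0)
  expect_identical(current_ratio(10, 5), 1)
  expect_identical(current_ratio(-10, -5), 1)
  expect_equal(current_ratio(-1, -5), -0.8)
  expect_error(current_ratio(1, 0), "zero baseline")
})

test_that("tip detection finds the constructed phase singularity", {
  fx <- generate_fixtures("rotating-phase-field", seed = 3, n = 41)
  tips <- detect_tips(fx$V1, fx$V2, dx = 0.03)
  expect_identical(nrow(tips), 1L)
  expect_equal(tips$x, fx$truth$x0, tolerance = 0.05)
  expect_equal(tips$y, fx$truth$y0, tolerance = 0.05)
  expect_identical(abs(tips$charge), 1)
})

test_that("planar fields contain no tips; mirrored pairs have zero net charge", {
  n <- 41
  plane <- matrix(rep(seq(-80, 20, length.out = n), n), n, n)
  expect_identical(nrow(detect_tips(plane, plane + 5, dx = 0.03)), 0L)
  # figure-of-eight: two mirrored singularities, charges cancel
  fx <- generate_fixtures("rotating-phase-field", seed = 3, n = 41)
  V1 <- cbind(fx$V1, fx$V1[, rev(seq_len(n))])
  V2 <- cbind(fx$V2, fx$V2[, rev(seq_len(n))])
  tips <- detect_tips(V1, V2, dx = 0.03)
  expect_identical(nrow(tips), 2L)
  expect_identical(sum(tips$charge), 0)
})

test_that("rotation counting unwraps the tip angle", {
  # circular path traversed once
  th <- seq(0, 2 * pi, length.out = 100)
  traj <- data.frame(t = seq_along(th), x = cos(th), y = sin(th))
  expect_equal(count_rotations(traj, center = c(0, 0))$rotations, 1,
               tolerance = 0.02)
  # stationary tip: no rotation
  still <- data.frame(t = 1:50, x = 1, y = 1)
  expect_equal(count_rotations(still, center = c(0, 0))$rotations, 0)
  # lost tip flags and counts up to the loss
  lost <- traj
  lost$x[60:100] <- NA
  r <- count_rotations(lost, center = c(0, 0))
  expect_true(r$lost)
  expect_lt(r$rotations, 1)
  expect_gt(r$rotations, 0.4)
})

test_that("outcome classification distinguishes the regimes", {
  period <- 100
  mk_traj <- function(x, y, t, n_tips = 1)
    data.frame(t = t, x = x, y = y, n_tips = n_tips, charge = 1)
  # stable far-away spiral, spot elsewhere -> unaffected
  t <- seq(0, 2000, 10)
  far <- mk_traj(1 + 0.1 * cos(t / 16), 1 + 0.1 * sin(t / 16), t)
  spots <- data.frame(x = 5, y = 5, radius = 0.45, t_on = 0, t_off = 2000)
  expect_identical(classify_outcome(far, spots, final_V = -80, period),
                   "unaffected")
  # tip resident in the spot for many rotations -> anchored
  near <- mk_traj(5 + 0.2 * cos(t / 16), 5 + 0.2 * sin(t / 16), t)
  expect_identical(classify_outcome(near, spots, final_V = -80, period),
                   "anchored")
  # anchored at two successive spot positions -> dragged
  spots2 <- data.frame(x = c(5, 4), y = c(5, 5), radius = 0.45,
                       t_on = c(0, 1000), t_off = c(1000, 2000))
  drag <- rbind(mk_traj(5 + 0.2 * cos(t[t < 1000] / 16),
                        5 + 0.2 * sin(t[t < 1000] / 16), t[t < 1000]),
                mk_traj(4 + 0.2 * cos(t[t >= 1000] / 16),
                        5 + 0.2 * sin(t[t >= 1000] / 16), t[t >= 1000]))
  expect_identical(classify_outcome(drag, spots2, final_V = -80, period),
                   "dragged")
  # tips gone and tissue quiescent -> terminated
  dead <- drag
  dead$n_tips[dead$t > 1400] <- 0L
  dead$x[dead$t > 1400] <- NA
  dead$y[dead$t > 1400] <- NA
  expect_identical(classify_outcome(dead, spots2, final_V = -80, period),
                   "terminated")
})

test_that("filament extraction recovers the extruded spiral", {
  fx <- generate_fixtures("extruded-spiral-volume", seed = 2, n = 41)
  fil <- extract_filament(fx$A1, fx$A2, dx = 0.03, dz = 0.03)
  expect_identical(length(fil), 1L)
  ch <- fil[[1]]
  expect_true(attr(ch, "transmural"))
  expect_equal(attr(ch, "length"), fx$truth$length, tolerance = 1e-6)
  # every layer's tip sits within one grid cell of the 2D tip
  expect_lt(max(abs(diff(ch$x))), 0.03 + 1e-9)
  expect_lt(max(abs(diff(ch$y))), 0.03 + 1e-9)
  # no reentry -> empty result
  flat <- array(-80, dim(fx$A1))
  expect_identical(length(extract_filament(flat, flat + 1)), 0L)
})
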