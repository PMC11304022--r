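test_that("equilibration reaches a drift-free resting state near -81 mV", {
  eq <- rest37()
  expect_true(eq$converged)
  expect_lt(eq$drift, 1e-3)
  # Table-1 conductances hyperpolarize slightly relative to the original
  # CRN resting potential of about -81 mV
  expect_gt(eq$state[["V"]], -85)
  expect_lt(eq$state[["V"]], -79)
  # equilibrating again from the fixed point stays put
  again <- step_cell(eq$state, healthy_params, 37, n = 5000)
  expect_equal(unname(again[["V"]]), unname(eq$state[["V"]]),
               tolerance = 1e-4)
})

test_that("an unstimulated cell does not drift from equilibrium", {
  eq <- rest37()
  r <- run_cell(healthy_params, 37, duration = 1000, stim_times = numeric(0),
                state0 = eq$state)
  expect_lt(max(abs(r$trace$V - eq$state[["V"]])), 0.01)
})

test_that("a suprathreshold stimulus elicits the baseline action potential", {
  m <- metrics37()
  expect_true(m$captured)
  expect_equal(unname(m$apd[["APD90"]]), 284, tolerance = 0.03)
  expect_gt(m$amplitude, 100)
  expect_true(m$apd[["APD90"]] >= m$apd[["APD50"]])
})

test_that("step halving leaves APD90 within 1%", {
  m1 <- metrics37()
  r2 <- run_cell(healthy_params, 37, duration = 600, stim_times = 10,
                 dt = 0.01)
  m2 <- ap_metrics(r2$trace, stim_times = 10)
  expect_equal(unname(m2$apd[["APD90"]]), unname(m1$apd[["APD90"]]),
               tolerance = 0.01)
})

test_that("dt above the explicit limit is rejected and blow-up is caught", {
  expect_error(step_cell(cell_state(), healthy_params, dt = 0.5), "0.02")
  expect_error(run_cell(healthy_params, 37, duration = 10, dt = 0.1), "0.02")
})

test_that("cooling elevates the resting potential linearly in T", {
  eqs <- lapply(c(5, 13, 21, 29, 37), function(T)
    equilibrate(healthy_params, T))
  rmp <- vapply(eqs, function(e) e$state[["V"]], numeric(1))
  Ts <- c(5, 13, 21, 29, 37)
  # +9 mV shift from 37 to 5 degC
  expect_equal(rmp[1] - rmp[5], 9, tolerance = 1)
  # monotone elevation with cooling, linear to R^2 >= 0.95
  expect_true(all(diff(rmp) < 0))
  fit <- lm(rmp ~ Ts)
  expect_gte(summary(fit)$r.squared, 0.95)
})

test_that("APD90 lengthens monotonically as temperature falls", {
  apd90 <- function(T, dur) {
    r <- run_cell(healthy_params, T, duration = dur, stim_times = 10)
    ap_metrics(r$trace, stim_times = 10)$apd[["APD90"]]
  }
  a <- c(apd90(37, 600), apd90(29, 1000), apd90(21, 2000), apd90(13, 5000))
  expect_true(all(diff(a) > 0))
})

test_that("the cold action potential reproduces the spike-dome metrology", {
  m37 <- metrics37()
  m5 <- metrics5()
  # ninefold APD90 prolongation at 5 degC
  expect_equal(round(m5$apd[["APD90"]] / m37$apd[["APD90"]]), 9)
  # APD40 collapses onto the early spike (first-crossing convention)
  expect_lt(m5$apd[["APD40"]], m37$apd[["APD40"]])
  # Ca transient peak roughly halved in the cold
  expect_lt(m5$cat_peak / m37$cat_peak, 0.75)
  expect_gt(m5$cat_peak / m37$cat_peak, 0.4)
})

test_that("peak INa falls about fivefold at 5 degC", {
  r37 <- run_cell(healthy_params, 37, duration = 60, stim_times = 10,
                  record_currents = TRUE, record_every = 1)
  r5 <- run_cell(healthy_params, 5, duration = 2000, stim_times = 10,
                 record_currents = TRUE, record_every = 5)
  f <- min(r37$trace$INa) / min(r5$trace$INa)
  expect_lte(f, 5)
  expect_gt(f, 3.5)
  # I_ratio for INa is negative in the cold
  expect_lt(current_ratio(min(r5$trace$INa) * -1, min(r37$trace$INa) * -1), 0)
})
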