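test_that("drag schedules walk straight to the target boundary", {
  prot <- drag_protocol(radius = 0.9, move_step = 1)
  # tip at the center of a 7.5-cm domain, nearest boundary to the left:
  # four interior positions then one abutting the boundary
  sch <- build_drag_schedule(c(3.75, 3.75), c(7.5, 7.5),
                             drag_protocol(move_step = 1,
                                           direction = c(-1, 0)))
  expect_identical(nrow(sch), 5L)
  expect_equal(sch$x, c(3.75, 2.75, 1.75, 0.75, 0))
  expect_equal(unique(sch$y), 3.75)
  # zero move vector: a static, anchor-only schedule
  sch0 <- build_drag_schedule(c(2, 2), c(7.5, 7.5),
                              drag_protocol(move_step = 0))
  expect_identical(nrow(sch0), 1L)
  # no tip, no schedule
  expect_error(build_drag_schedule(c(NA, 2), c(7.5, 7.5), prot),
               "without a detected tip")
})

test_that("protocol validation rejects unphysical settings", {
  expect_error(drag_protocol(radius = -1))
  expect_error(drag_protocol(T_spot = 50))
  expect_error(drag_protocol(move_step = -0.5))
  p <- drag_protocol(radius = 0.45)
  expect_equal(p$anchor_margin, max(0.1, 0.2 * 0.45))
})

test_that("anchor-only schedules cannot classify as dragged", {
  # structural property via the classifier: a single spot position can
  # produce at most "anchored"
  t <- seq(0, 3000, 10)
  traj <- data.frame(t = t, x = 2 + 0.2 * cos(t / 20),
                     y = 2 + 0.2 * sin(t / 20), charge = 1, n_tips = 1)
  spots <- data.frame(x = 2, y = 2, radius = 0.45, t_on = 0, t_off = 3000)
  out <- classify_outcome(traj, spots, final_V = -80, period_ms = 126)
  expect_identical(out, "anchored")
})
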