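test_that("tangential offset cancels the curvature-following yaw rate", {
  expect_lt(abs(tangential_offset(8, 80) - 5.73), 0.005)
  expect_lt(abs(tangential_offset(26.82, 500) - 3.07), 0.005)
  expect_equal(tangential_offset(10, Inf), 0)
  # unit consistency: offset (rad/s) times radius recovers the speed
  expect_equal(tangential_offset(8, 80) * pi / 180 * 80, 8)
  expect_error(tangential_offset(-1, 80), "speed")
  expect_error(tangential_offset(8, 0), "bend_radius")
})

test_that("smooth step ramps C1-continuously from 0 to 1", {
  expect_equal(smooth_step(6, onset = 6), 0)
  expect_equal(smooth_step(6.5, onset = 6), 1)
  expect_equal(smooth_step(10, onset = 6), 1)
  expect_equal(smooth_step(5, onset = 6), 0)
  # odd symmetry about the ramp midpoint
  expect_equal(smooth_step(6.25, onset = 6), 0.5)
  u <- smooth_step(seq(6, 6.5, by = 0.01), onset = 6)
  expect_true(all(diff(u) >= 0))
  expect_error(smooth_step(1, 0, duration = 0), "duration")
})

test_that("zero-offset trajectories follow the centreline exactly", {
  geom <- road_geometry()
  sp <- failure_spec(tlc_f = 5, onset = 6, yaw_offset = 0)
  tr <- simulate_failure(sp, geom, horizon = 15)
  expect_lt(max(abs(tr$lateral_offset)), 1e-6)
  expect_identical(time_to_lane_crossing(tr, geom, 6), Inf)
})

test_that("off-tangent crossing matches the closed form across radii", {
  for (R in c(80, 300, 500, 2000)) {
    v <- 8; d <- 1.5
    geom <- road_geometry(straight_length = 0, bend_radius = R,
                          road_width = 3, speed = v)
    sp <- failure_spec(tlc_f = 1, onset = 0,
                       yaw_offset = tangential_offset(v, R))
    tr <- simulate_failure(sp, geom, dt = 1 / 60,
                           horizon = offtangent_closed_form(R, v, d) + 3,
                           ramp_duration = 0)
    expect_equal(time_to_lane_crossing(tr, geom, 0),
                 offtangent_closed_form(R, v, d), tolerance = 0.02)
  }
})

test_that("tangential failure heading grows linearly with arc angle", {
  geom <- road_geometry()
  sp <- failure_spec(tlc_f = 2, onset = 6,
                     yaw_offset = tangential_offset(8, 80))
  tr <- simulate_failure(sp, geom, horizon = 9, ramp_duration = 0)
  # after onset the vehicle travels straight: heading error relative to the
  # road tangent grows at the road's angular rate v/R
  post <- tr$time > 6.2 & tr$time < 8
  rate <- diff(range(tr$heading_error[post])) / diff(range(tr$time[post]))
  expect_equal(abs(rate), 8 / 80, tolerance = 0.02)
})

test_that("drift direction matches the failure specification", {
  for (dir in c("understeer", "oversteer")) for (bend in c("left", "right")) {
    geom <- road_geometry(bend_direction = bend)
    sp <- failure_spec(tlc_f = 3, onset = 6, yaw_offset = 3, direction = dir)
    tr <- simulate_failure(sp, geom, horizon = 12)
    final <- tr$lateral_offset[nrow(tr)]
    if (dir == "understeer") expect_lt(final, 0) else expect_gt(final, 0)
  }
})

test_that("crossing time is non-increasing in the offset magnitude", {
  geom <- road_geometry()
  tlcs <- vapply(c(1, 2, 4, 6), function(off) {
    sp <- failure_spec(tlc_f = 3, onset = 6, yaw_offset = off)
    time_to_lane_crossing(simulate_failure(sp, geom, horizon = 30), geom, 6)
  }, numeric(1))
  expect_true(all(diff(tlcs) <= 0))
})

test_that("offset solver round-trips targets and orders offsets", {
  geom <- road_geometry()
  offs <- vapply(c(3, 5, 9), function(target) {
    off <- solve_offset_for_tlc(target, geom, onset = 6)
    sp <- failure_spec(target, 6, off)
    tlc <- time_to_lane_crossing(simulate_failure(sp, geom, horizon = 25),
                                 geom, 6)
    expect_lt(abs(tlc - target), 0.01)
    off
  }, numeric(1))
  expect_true(all(diff(offs) < 0)) # more gradual failures need smaller biases
  expect_error(solve_offset_for_tlc(0.05, geom), "not achievable")
})

test_that("trial-end censoring threshold is the bookkeeping identity", {
  expect_equal(tlc_end(9.55, 6, 15), 0.55)
  expect_equal(tlc_end(2.23, 6, 15), -6.77)
  expect_equal(tlc_end(4, 15, 15), 4)
  expect_error(tlc_end(4, 16, 15), "trial_length")
})

test_that("road-design scenarios place off-tangent failures correctly", {
  expect_equal(scenario_tlc(500, 60, 3.65, "mph"), 1.6, tolerance = 0.02)
  expect_equal(scenario_tlc(2000, 70, 3.65, "mph"), 2.7, tolerance = 0.04)
  expect_identical(scenario_tlc(Inf, 30, 3.65, "ms"), Inf)
})

test_that("sobol points reproduce the reference sequence", {
  # frozen from an independent quasi-Monte-Carlo implementation
  ref <- matrix(c(
    0, 0, 0, 0,
    0.5, 0.5, 0.5, 0.5,
    0.75, 0.25, 0.25, 0.25,
    0.25, 0.75, 0.75, 0.75,
    0.375, 0.375, 0.625, 0.875,
    0.875, 0.875, 0.125, 0.375,
    0.625, 0.125, 0.875, 0.625,
    0.125, 0.625, 0.375, 0.125,
    0.1875, 0.3125, 0.9375, 0.4375,
    0.6875, 0.8125, 0.4375, 0.9375,
    0.9375, 0.0625, 0.6875, 0.1875,
    0.4375, 0.5625, 0.1875, 0.6875,
    0.3125, 0.1875, 0.3125, 0.5625,
    0.8125, 0.6875, 0.8125, 0.0625,
    0.5625, 0.4375, 0.0625, 0.8125,
    0.0625, 0.9375, 0.5625, 0.3125), 16, 4, byrow = TRUE)
  expect_equal(sobol_points(16, 4), ref)
  expect_equal(sobol_points(4, 4, skip = 4), ref[5:8, ])
})

test_that("sobol condition generation maps ranges and proportions", {
  cond <- sobol_conditions(24, solve_offsets = FALSE)
  expect_true(all(cond$tlc_f_s >= 2.95 & cond$tlc_f_s <= 19.51))
  expect_true(all(cond$onset_s >= 5 & cond$onset_s <= 9))
  expect_true(all(cond$trajectory_id %in% 1:4))
  big <- sobol_conditions(1000, solve_offsets = FALSE)
  expect_gt(mean(big$direction == "understeer"), 0.67)
  expect_lt(mean(big$direction == "understeer"), 0.73)
  # determinism
  expect_identical(sobol_conditions(24, solve_offsets = FALSE),
                   sobol_conditions(24, solve_offsets = FALSE))
  # full study design: 4 Repeated + 24 Non-Repeated conditions
  conds <- failure_conditions(solve_offsets = FALSE)
  expect_equal(nrow(conds), 28)
  expect_equal(sum(conds$repeated_flag), 4)
})
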