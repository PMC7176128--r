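test_that("schedule specs parse into contiguous frames with the right totals", {
  s <- make_schedule("8x15,2x30,2x60,3x300")
  expect_equal(nrow(s), 15)
  expect_equal(schedule_duration(s), 1200)
  expect_equal(s$start_s[1], 0)
  expect_equal(s$start_s[-1], (s$start_s + s$duration_s)[-nrow(s)])
  expect_equal(attr(s, "label"), "8x15-2x30-2x60-3x300")

  s2 <- make_schedule("10x30,3x300")
  expect_equal(nrow(s2), 13)
  expect_equal(schedule_duration(s2), 1200)

  # all five reference schedules span exactly 20 minutes
  for (sp in reference_schedules()) {
    expect_equal(schedule_duration(make_schedule(sp)), 1200)
  }
})

test_that("malformed schedule specs are rejected with the offending group named", {
  expect_error(make_schedule("0x15"), "0x15")
  expect_error(make_schedule("3x0"), "3x0")
  expect_error(make_schedule("8x15,banana"), "banana")
  expect_error(make_schedule(""), "malformed|empty")
  expect_error(make_schedule("4x2.5", grid_step = 1), "multiple")
})

test_that("binning averages a constant exactly and a ramp to its midpoint", {
  s <- make_schedule("4x10,2x30")
  const <- continuous_curve(rep(7, 101))
  expect_equal(bin_curve(const, s)$values, rep(7, 6))

  ramp <- continuous_curve(seq(0, 100), 1)
  b <- bin_curve(ramp, s)
  expect_equal(b$values[1], 5) # mean of t over [0,10)
  expect_equal(b$values, s$mid_s)
  expect_equal(b$frame_mid_s, s$start_s + s$duration_s / 2)
})

test_that("binning agrees with independent per-frame quadrature on a smooth curve", {
  t <- seq(0, 1200)
  curve <- continuous_curve(10 * exp(-t / 300) + 2 * sin(t / 100) + 3, 1)
  s <- make_schedule("8x15,2x30,2x60,3x300")
  b <- bin_curve(curve, s)
  # trapezoid-rule oracle, computed frame by frame from scratch
  oracle <- vapply(seq_len(nrow(s)), function(i) {
    idx <- (s$start_s[i]):(s$end_s[i])
    v <- curve$values[idx + 1]
    sum(diff(idx) * (head(v, -1) + tail(v, -1)) / 2) / s$duration_s[i]
  }, numeric(1))
  expect_lt(max(abs(b$values - oracle) / oracle), 1e-3)
})

test_that("duration-weighted frame sums conserve the curve integral", {
  t <- seq(0, 1200)
  curve <- continuous_curve(5 + 20 * exp(-((t - 40) / 25)^2) + t / 500, 1)
  total <- sum(diff(t) * (head(curve$values, -1) + tail(curve$values, -1)) / 2)
  for (sp in reference_schedules()) {
    s <- make_schedule(sp)
    b <- bin_curve(curve, s)
    expect_lt(abs(sum(b$values * s$duration_s) - total) / total, 1e-3)
  }
})

test_that("re-binning a frame-wise-constant curve reproduces the frame values", {
  s <- make_schedule("4x15,2x30,1x60")
  vals <- c(3, 8, 1, 6, 4, 9, 2)
  # step curve sampled on the 1-s grid, boundary node carrying the new frame
  step_vals <- vals[findInterval(seq(0, 180), s$start_s)]
  rebinned <- bin_curve(continuous_curve(step_vals, 1), s)$values
  # exact up to the boundary half-cell of the piecewise-linear representation:
  # each frame can differ by at most |jump| * step / (2 * duration)
  bound <- max(abs(diff(vals))) * 1 / (2 * min(s$duration_s))
  expect_lt(max(abs(rebinned - vals)), bound + 1e-12)
  # and a constant curve re-bins exactly
  expect_equal(bin_curve(continuous_curve(rep(4, 181), 1), s)$values, rep(4, 7))
})

test_that("binning a too-short curve is a coverage error", {
  expect_error(bin_curve(continuous_curve(rep(1, 100), 1),
                         make_schedule("8x15,2x30,2x60,3x300")),
               "spans only")
})

test_that("bolus arrival is the start of the first supra-threshold frame", {
  s <- make_schedule("20x3")
  v <- rep(0, 20)
  v[9] <- 50 # 9th frame (1-based) starts at 24 s
  expect_equal(detect_bolus_arrival(sampled_tac(s, v)), 24)

  # flat nonzero TAC: nothing exceeds baseline
  expect_error(detect_bolus_arrival(sampled_tac(s, rep(5, 20))), "not found")

  # synthetic bolus with known onset 15 s recovered within one frame width
  wb <- synth_bolus(amplitude = 30, t_peak = 35, onset = 15, duration = 60)
  tac <- bin_curve(wb, s)
  arrival <- detect_bolus_arrival(tac)
  expect_lte(abs(arrival - 15), 3)
})

test_that("TAC CSV round-trips frames and values", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tac <- fixture_tac()
  write_tac_csv(tac, tmp)
  back <- read_tac_csv(tmp)
  expect_equal(back$values, tac$values, tolerance = 1e-8)
  expect_equal(back$schedule$start_s, tac$schedule$start_s)
  expect_equal(attr(back$schedule, "label"), "8x15-2x30-2x60-3x300")
})
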