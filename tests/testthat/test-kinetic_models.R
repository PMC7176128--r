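test_that("single-tissue model degenerates correctly at K1=0 and VB=1", {
  inp <- fixture_input
  p0 <- kinetic_params("1T2k+VB", K1 = 0, k2 = 0.087, VB = 0.084)
  out <- simulate_1t2k_vb(p0, inp, 1200)
  expect_equal(out$values, 0.084 * inp$plasma_parent$values)

  p1 <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 1)
  expect_equal(simulate_1t2k_vb(p1, inp, 1200)$values, inp$plasma_parent$values)
})

test_that("grid convolution matches the analytic biexponential closed form", {
  # Cp(t) = exp(-t) in minutes, VB = 0: C(t) = K1 (e^{-k2 t} - e^{-t})/(1 - k2)
  t_min <- seq(0, 1200) / 60
  cp <- continuous_curve(exp(-t_min), 1)
  for (pars in list(c(K1 = 0.161, k2 = 0.087), c(K1 = 0.5, k2 = 0.3))) {
    sim <- simulate_1t2k_vb(
      kinetic_params("1T2k+VB", K1 = pars["K1"], k2 = pars["k2"], VB = 0),
      cp, 1200)
    closed <- pars["K1"] * (exp(-pars["k2"] * t_min) - exp(-t_min)) /
      (1 - pars["k2"])
    expect_lt(max(abs(sim$values - closed)) / max(closed), 0.002)
  }
})

test_that("the three models nest", {
  inp <- fixture_input
  ref <- simulate_1t2k_vb(fixture_params, inp, 1200)$values
  p44 <- kinetic_params("2T4k+VB", K1 = 0.161, k2 = 0.087, k3 = 0, k4 = 0,
                        VB = 0.084)
  expect_lt(max(abs(simulate_2t(p44, inp, 1200)$values - ref)) / max(ref), 1e-3)

  # 2T4k with k4 = 0 reproduces 2T3k
  p43 <- kinetic_params("2T4k+VB", K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0,
                        VB = 0.05)
  p33 <- kinetic_params("2T3k+VB", K1 = 0.2, k2 = 0.1, k3 = 0.05, VB = 0.05)
  a <- simulate_2t(p43, inp, 1200)$values
  b <- simulate_2t(p33, inp, 1200)$values
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("irreversible 2T3k traps tracer: tissue settles onto a positive plateau", {
  # tail-free bolus input forced to zero after 200 s
  v <- synth_bolus(30, t_peak = 30, tail_frac = c(0, 0))$values
  v[seq(0, 1200) > 200] <- 0
  cp <- continuous_curve(v, 1)
  K1 <- 0.2; k2 <- 0.1; k3 <- 0.08
  p <- kinetic_params("2T3k+VB", K1 = K1, k2 = k2, k3 = k3, VB = 0)
  out <- simulate_2t(p, cp, 1200)$values
  # with k4 = 0 there is no efflux from the trapped pool: once the input has
  # cleared the free pool washes out monotonically onto the trapped asymptote
  # C(inf) = (K1/60) * k3/(k2+k3) * integral(Cp dt)
  asym <- (K1 / 60) * k3 / (k2 + k3) * sum((head(v, -1) + tail(v, -1)) / 2)
  late <- out[seq(0, 1200) > 250]
  expect_true(all(diff(late) <= 1e-9))
  expect_true(all(late >= asym - 1e-9))
  expect_lt(abs(out[1201] - asym) / asym, 0.1)
})

test_that("two-tissue simulation matches a high-accuracy adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  inp <- fixture_input
  cp <- inp$plasma_parent
  f <- approxfun(seq(0, 1200), cp$values, rule = 2)
  for (pp in list(c(0.3, 0.15, 0.08, 0.02, 0.05),
                  c(0.161, 0.087, 0.05, 0, 0.084))) {
    kp <- kinetic_params("2T4k+VB", K1 = pp[1], k2 = pp[2], k3 = pp[3],
                         k4 = pp[4], VB = pp[5])
    ode <- deSolve::lsoda(
      c(C1 = 0, C2 = 0), seq(0, 1200),
      function(t, y, p) {
        list(c(p[1] * f(t) - (p[2] + p[3]) * y[1] + p[4] * y[2],
               p[3] * y[1] - p[4] * y[2]))
      },
      pp[1:4] / 60, rtol = 1e-10, atol = 1e-12)
    ref <- pp[5] * cp$values + (1 - pp[5]) * (ode[, "C1"] + ode[, "C2"])
    sim <- simulate_2t(kp, inp, 1200)$values
    expect_lt(max(abs(sim - ref)) / max(ref), 0.002)
  }
})

test_that("all models are linear in the input and preserve non-negativity", {
  inp <- fixture_input$plasma_parent
  scaled <- continuous_curve(2.5 * inp$values, 1)
  for (kp in list(fixture_params,
                  kinetic_params("2T3k+VB", K1 = 0.2, k2 = 0.1, k3 = 0.05,
                                 VB = 0.05),
                  kinetic_params("2T4k+VB", K1 = 0.2, k2 = 0.1, k3 = 0.05,
                                 k4 = 0.02, VB = 0.05))) {
    a <- simulate_model(kp, inp, 1200)$values
    b <- simulate_model(kp, scaled, 1200)$values
    expect_equal(b, 2.5 * a, tolerance = 1e-10)
    expect_true(all(a >= -1e-9))
  }
})

test_that("parameter validation rejects non-physical values", {
  expect_error(kinetic_params("1T2k+VB", K1 = -0.1, k2 = 0.1), "K1")
  expect_error(kinetic_params("1T2k+VB", K1 = 0.1, k2 = 0.1, VB = 1.2), "VB")
  expect_equal(distribution_volume(fixture_params), 0.161 / 0.087)
})
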