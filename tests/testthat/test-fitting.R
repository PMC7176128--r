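test_that("noiseless TACs refit to the generating parameters on every schedule", {
  for (sp in reference_schedules()) {
    f <- fit_model(fixture_tac(spec = sp), fixture_input, "1T2k+VB")
    expect_true(f$converged)
    expect_lt(abs(f$params$K1 - 0.161) / 0.161, 0.01)
    expect_lt(abs(f$params$k2 - 0.087) / 0.087, 0.01)
    expect_lt(abs(f$params$VB - 0.084) / 0.084, 0.01)
  }
})

test_that("starting at the truth on noiseless data leaves ss at machine scale", {
  opts <- fit_options(init = c(K1 = 0.161, k2 = 0.087, k3 = 0.05, k4 = 0.01,
                               VB = 0.084))
  f <- fit_model(fixture_tac(), fixture_input, "1T2k+VB", opts)
  expect_true(f$converged)
  expect_lt(f$ss, 1e-12)
})

test_that("the reversible 2T fit collapses onto 1T truth on 1T-generated data", {
  f <- fit_model(fixture_tac(), fixture_input, "2T4k+VB")
  expect_lt(f$params$k3, 1e-3)
  expect_lt(abs(f$params$K1 - 0.161) / 0.161, 0.02)
})

test_that("underdetermined fits are refused", {
  tac <- fixture_tac(spec = "3x400")
  expect_error(fit_model(tac, fixture_input, "1T2k+VB"), "underdetermined")
})

test_that("duration weighting changes the objective but not the noiseless optimum", {
  f <- fit_model(fixture_tac(), fixture_input, "1T2k+VB",
                 fit_options(weights = "duration"))
  expect_lt(abs(f$params$K1 - 0.161) / 0.161, 0.01)
})

test_that("AICc reproduces its formula, is monotone in ss, and loses its correction as n grows", {
  expect_equal(aicc(ss = 15, n = 15, k = 3), 6 + 24 / 11)
  expect_lt(aicc(7.5, 15, 3), aicc(15, 15, 3))
  # brute-force evaluation over random tuples
  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:60, 1); k <- sample(2:5, 1); ss <- runif(1, 0.01, 50)
    expect_equal(aicc(ss, n, k),
                 n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  n <- 1e7
  expect_lt(abs(aicc(n, n, 3) - (n * log(1) + 6)), 1e-4)
  expect_error(aicc(1, 4, 3), "n > k")
  expect_error(aicc(0, 15, 3), "positive")
})

test_that("model selection takes the lowest AICc and breaks ties toward parsimony", {
  mk <- function(aicc, k, id) {
    structure(list(aicc = aicc, n_params = k, model_id = id),
              class = "fit_result")
  }
  expect_equal(select_model(list(mk(8.2, 3, "1T2k+VB"),
                                 mk(11.0, 5, "2T4k+VB")))$model_id, "1T2k+VB")
  expect_equal(select_model(list(mk(8.2, 5, "2T4k+VB"),
                                 mk(8.2, 3, "1T2k+VB")))$model_id, "1T2k+VB")
  expect_error(select_model(list()), "at least one")
})

test_that("Levenberg-Marquardt recovers K1 to a few percent under moderate noise", {
  tac0 <- fixture_tac()
  rel_err <- numeric(100)
  for (r in 1:100) {
    set.seed(5000 + r)
    noisy <- add_poisson_frame_noise(tac0, 1.5)
    f <- fit_model(noisy, fixture_input, "1T2k+VB")
    rel_err[r] <- abs(f$params$K1 - 0.161) / 0.161
  }
  expect_lt(median(rel_err), 0.05)
})

test_that("Logan analysis recovers the distribution volume of reversible 1T kinetics", {
  p <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0)
  tac <- bin_curve(simulate_1t2k_vb(p, fixture_input, 1200),
                   make_schedule("40x30"))
  lg <- logan_vt(tac, fixture_input, t_star = 600)
  expect_lt(abs(lg$vt - 0.161 / 0.087) / (0.161 / 0.087), 0.05)
  expect_gt(lg$r2, 0.999)
  expect_gte(lg$n_points, 3)
})

test_that("Logan plot of a curve against itself has unit slope and zero intercept", {
  sched <- make_schedule("40x30")
  cp <- fixture_input$plasma_parent
  tac <- bin_curve(cp, sched)
  lg <- logan_vt(tac, cp, t_star = 600)
  expect_equal(lg$vt, 1, tolerance = 1e-8)
  expect_equal(lg$intercept, 0, tolerance = 1e-8)
})

test_that("doubling the plasma curve halves the Logan slope", {
  p <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0)
  tac <- bin_curve(simulate_1t2k_vb(p, fixture_input, 1200),
                   make_schedule("40x30"))
  cp <- fixture_input$plasma_parent
  lg1 <- logan_vt(tac, cp, t_star = 600)
  lg2 <- logan_vt(tac, continuous_curve(2 * cp$values, 1), t_star = 600)
  expect_equal(lg2$vt, lg1$vt / 2, tolerance = 1e-10)
})

test_that("Logan guards its window: too few points and non-positive values error", {
  p <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0)
  tac <- fixture_tac(p)
  expect_error(logan_vt(tac, fixture_input, t_star = 600), "fewer than 3")
  sched <- make_schedule("40x30")
  bad <- sampled_tac(sched, rep(c(1, 0), 20))
  expect_error(logan_vt(bad, fixture_input, t_star = 600), "non-positive")
})

test_that("automatic t_star picks a tail window that is actually linear", {
  p <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0)
  tac <- bin_curve(simulate_1t2k_vb(p, fixture_input, 1200),
                   make_schedule("40x30"))
  lg <- logan_vt(tac, fixture_input, t_star = "auto")
  expect_lt(abs(lg$vt - 0.161 / 0.087) / (0.161 / 0.087), 0.1)
})
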