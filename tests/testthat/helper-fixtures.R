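# Shared fixtures: a default synthetic plasma input function and the
# cohort-mean single-tissue parameters used throughout the tests.

fixture_input <- apply_corrections(synth_bolus(amplitude = 30, t_peak = 35))

fixture_params <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0.084)

optimal_spec <- "8x15,2x30,2x60,3x300"
coarse_spec <- "4x45,3x90,5x150"

fixture_tac <- function(params = fixture_params, spec = optimal_spec,
                        input = fixture_input) {
  bin_curve(simulate_1t2k_vb(params, input, 1200), make_schedule(spec))
}

# exhaustive-null Wilcoxon signed-rank oracle: enumerate all sign patterns of
# the |differences| ranks and compare the positive-rank sum to the observed
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% rk)
  p <- 2 * min(mean(stats <= obs), mean(stats >= obs))
  min(1, p)
}
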