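#' Kinetic parameter sets for the three compartment models
#'
#' The package supports the three VOI-level compartment models most used for
#' full kinetic analysis of oncology PET tracers: the reversible single-tissue
#' model with blood volume (`"1T2k+VB"`), and the irreversible (`"2T3k+VB"`,
#' k4 = 0) and reversible (`"2T4k+VB"`) two-tissue models. `K1` (mL/ccm/min)
#' is the rate constant from blood to tissue, `k2` (1/min) from tissue back to
#' blood, `k3`/`k4` (1/min) exchange with the second tissue pool, and `VB` the
#' fractional blood volume. The distribution volume of the single-tissue model
#' is `DV = K1/k2`.
#'
#' @param model_id One of `"1T2k+VB"`, `"2T3k+VB"`, `"2T4k+VB"`.
#' @param K1,k2,k3,k4 Rate constants, per minute; all non-negative. `k3`,`k4`
#'   are ignored for `"1T2k+VB"`; `k4` is forced to 0 for `"2T3k+VB"`.
#' @param VB Blood volume fraction in `[0, 1)`.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(model_id = "1T2k+VB", K1, k2, k3 = 0, k4 = 0, VB = 0) {
  model_id <- match.arg(model_id, c("1T2k+VB", "2T3k+VB", "2T4k+VB"))
  if (model_id == "1T2k+VB") { k3 <- 0; k4 <- 0 }
  if (model_id == "2T3k+VB") k4 <- 0
  stopifnot(K1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0)
  if (VB < 0 || VB > 1) stop("VB must lie in [0, 1]", call. = FALSE)
  structure(list(model_id = model_id, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 VB = VB),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> %s: K1=%.4g mL/ccm/min, k2=%.4g/min", x$model_id,
              x$K1, x$k2))
  if (x$model_id != "1T2k+VB") cat(sprintf(", k3=%.4g/min", x$k3))
  if (x$model_id == "2T4k+VB") cat(sprintf(", k4=%.4g/min", x$k4))
  cat(sprintf(", VB=%.3g\n", x$VB))
  invisible(x)
}

#' Distribution volume K1/k2 of a parameter set
#' @param params A `kinetic_params` with `k2 > 0`.
#' @export
distribution_volume <- function(params) {
  stopifnot(inherits(params, "kinetic_params"), params$k2 > 0)
  params$K1 / params$k2
}

# resolve the curve feeding the convolution and the curve feeding the VB term.
# By default the single metabolite-corrected plasma curve plays both roles,
# exactly as the model TAC equation is written; vb_curve overrides the VB term.
resolve_input <- function(input, vb_curve = NULL) {
  cp <- if (inherits(input, "input_function")) input$plasma_parent else input
  stopifnot(inherits(cp, "continuous_curve"))
  cb <- if (is.null(vb_curve)) cp else vb_curve
  stopifnot(inherits(cb, "continuous_curve"), cb$step == cp$step,
            length(cb$values) == length(cp$values))
  list(cp = cp, cb = cb)
}

# trapezoid-weighted discrete convolution of a sampled curve with kernel
# values on the same grid: y_n = h * [sum_{j=0..n} x_j k_{n-j}
#                                     - (x_0 k_n + x_n k_0)/2]
conv_trapz <- function(x, kern, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
  h * (full - 0.5 * (x[1] * kern + x * kern[1]))
}

#' Forward-simulate the reversible single-tissue model (1T2k+VB)
#'
#' Computes `C(t) = VB * C_IDIF(t) + (1 - VB) * K1 * exp(-k2 t) (x) C_IDIF(t)`
#' on the input curve's fine grid, with rates converted from per-minute to
#' per-second at this boundary and the convolution discretized by the
#' trapezoidal rule. This discretization is the single forward-model truth
#' used both for simulation and inside the fitter.
#'
#' @param params A `kinetic_params` with `model_id = "1T2k+VB"`.
#' @param input An `input_function` (its metabolite-corrected `plasma_parent`
#'   is used) or a bare `continuous_curve`.
#' @param duration Simulation length in seconds (default: input span).
#' @param vb_curve Optional separate curve (e.g. whole blood) for the VB term;
#'   default is the same curve as the convolution, per the model equation.
#' @return A `continuous_curve` of tissue concentration (kBq/mL).
#' @export
simulate_1t2k_vb <- function(params, input, duration = NULL, vb_curve = NULL) {
  stopifnot(inherits(params, "kinetic_params"), params$model_id == "1T2k+VB")
  cv <- resolve_input(input, vb_curve)
  vals <- forward_model(params, cv$cp$values, cv$cb$values, cv$cp$step)
  crop_curve(continuous_curve(vals, cv$cp$step), duration)
}

#' Forward-simulate the two-tissue models (2T3k+VB, 2T4k+VB)
#'
#' Solves `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2` with zero initial conditions and returns
#' `C(t) = VB * C_IDIF + (1 - VB) * (C1 + C2)`. The tissue impulse response is
#' resolved analytically into (at most) two exponentials, which are convolved
#' with the input on the fine grid like the single-tissue model; the repeated
#' eigenvalue case falls back to the confluent `t * exp(-a t)` kernel.
#'
#' @inheritParams simulate_1t2k_vb
#' @param params A `kinetic_params` with a two-tissue `model_id`.
#' @export
simulate_2t <- function(params, input, duration = NULL, vb_curve = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            params$model_id %in% c("2T3k+VB", "2T4k+VB"))
  cv <- resolve_input(input, vb_curve)
  vals <- forward_model(params, cv$cp$values, cv$cb$values, cv$cp$step)
  crop_curve(continuous_curve(vals, cv$cp$step), duration)
}

#' Forward-simulate any of the three models
#' @inheritParams simulate_1t2k_vb
#' @export
simulate_model <- function(params, input, duration = NULL, vb_curve = NULL) {
  if (params$model_id == "1T2k+VB") {
    simulate_1t2k_vb(params, input, duration, vb_curve)
  } else {
    simulate_2t(params, input, duration, vb_curve)
  }
}

# core forward model on raw vectors (hot path of the fitter): cp drives the
# convolution, cb the blood-volume term, h is the grid step in seconds
forward_model <- function(params, cp, cb, h) {
  t_s <- (seq_along(cp) - 1) * h
  K1 <- params$K1 / 60 # per-second
  if (params$model_id == "1T2k+VB") {
    k2 <- params$k2 / 60
    tissue <- if (K1 == 0) numeric(length(cp)) else {
      conv_trapz(cp, K1 * exp(-k2 * t_s), h)
    }
  } else {
    k2 <- params$k2 / 60; k3 <- params$k3 / 60; k4 <- params$k4 / 60
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
    tissue <- if (K1 == 0) {
      numeric(length(cp))
    } else if (disc > 1e-18) {
      rt <- sqrt(disc)
      a1 <- (s - rt) / 2
      a2 <- (s + rt) / 2
      c1 <- (k3 + k4 - a1) / (a2 - a1)
      c2 <- (a2 - k3 - k4) / (a2 - a1)
      conv_trapz(cp, K1 * (c1 * exp(-a1 * t_s) + c2 * exp(-a2 * t_s)), h)
    } else {
      a <- s / 2 # repeated eigenvalue: impulse response K1 e^{-at}(1+(k3+k4-a)t)
      conv_trapz(cp, K1 * exp(-a * t_s) * (1 + (k3 + k4 - a) * t_s), h)
    }
  }
  params$VB * cb + (1 - params$VB) * tissue
}

crop_curve <- function(curve, duration) {
  if (is.null(duration)) return(curve)
  n <- round(duration / curve$step) + 1L
  stopifnot(n >= 2L, n <= length(curve$values))
  continuous_curve(curve$values[seq_len(n)], curve$step)
}
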