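#' Synthesize a bolus-shaped arterial whole-blood curve
#'
#' Stand-in generator for an image-derived input function (IDIF): a
#' gamma-variate first pass plus a biexponential recirculation tail that ramps
#' in over roughly the peak time. The curve is zero before `onset`, rises to a
#' single maximum near `onset + t_peak` and decays toward a slowly varying
#' tail. The curve is rescaled so its maximum equals `amplitude` exactly.
#'
#' @param amplitude Peak whole-blood concentration, kBq/mL (> 0).
#' @param t_peak Time from onset to the gamma-variate peak, seconds.
#' @param onset Appearance time of the bolus, seconds (default 0: the curve
#'   is already re-zeroed to bolus arrival).
#' @param alpha Gamma-variate shape (> 0); larger is more symmetric.
#' @param tail_frac Two recirculation amplitudes as fractions of the peak.
#' @param tail_lambda Two tail decay rates, 1/s (both > 0, fast then slow).
#' @param tail_tau Tail ramp-in time constant, seconds.
#' @param grid_step Output grid step, seconds (default 1).
#' @param duration Total curve duration, seconds (default 1200).
#' @return A `continuous_curve`.
#' @examples
#' wb <- synth_bolus(30, t_peak = 35)
#' max(wb$values)  # 30
#' @export
synth_bolus <- function(amplitude = 30, t_peak = 35, onset = 0, alpha = 3,
                        tail_frac = c(0.25, 0.15),
                        tail_lambda = c(0.01, 5e-4),
                        tail_tau = 30,
                        grid_step = 1, duration = 1200) {
  stopifnot(amplitude > 0, t_peak > 0, t_peak < duration, onset >= 0,
            alpha > 0, length(tail_frac) == 2, length(tail_lambda) == 2,
            tail_tau > 0, grid_step > 0, duration > grid_step)
  if (any(tail_lambda <= 0) || any(tail_frac < 0)) {
    stop("tail decay rates must be positive and tail fractions non-negative",
         call. = FALSE)
  }
  t <- seq(0, duration, by = grid_step)
  v <- bolus_shape(t, onset, t_peak, alpha, tail_frac, tail_lambda, tail_tau)
  continuous_curve(amplitude * v / max(v), step = grid_step)
}

# unit-peak-gamma-variate + ramped biexponential tail, evaluated at times t
bolus_shape <- function(t, onset, t_peak, alpha, tail_frac, tail_lambda, tail_tau) {
  s <- pmax(t - onset, 0)
  gv <- (s / t_peak)^alpha * exp(alpha * (1 - s / t_peak))
  tail <- (1 - exp(-s / tail_tau)) *
    (tail_frac[1] * exp(-tail_lambda[1] * s) +
     tail_frac[2] * exp(-tail_lambda[2] * s))
  ifelse(s > 0, gv + tail, 0)
}

# closed-form time integral of bolus_shape from onset to onset+T (unit peak),
# via the lower incomplete gamma function; used as an analytic oracle
bolus_shape_integral <- function(T, t_peak, alpha, tail_frac, tail_lambda, tail_tau) {
  # int_0^T (s/tp)^a exp(a(1-s/tp)) ds = e^a (tp/a)^(a+1)/tp^a * gammainc(a+1, aT/tp)
  g <- exp(alpha) * t_peak / alpha^(alpha + 1) * gamma(alpha + 1) *
    stats::pgamma(alpha * T / t_peak, shape = alpha + 1)
  tail_int <- function(f, lam) {
    f * ((1 - exp(-lam * T)) / lam -
         (1 - exp(-(lam + 1 / tail_tau) * T)) / (lam + 1 / tail_tau))
  }
  g + tail_int(tail_frac[1], tail_lambda[1]) + tail_int(tail_frac[2], tail_lambda[2])
}

#' Build a plasma input function from a whole-blood curve
#'
#' Applies the two standard corrections that turn a whole-blood IDIF into the
#' plasma parent-tracer input the kinetic models need: hematocrit correction
#' (division by `1 - hct`, the tracer being plasma-borne) and metabolite
#' correction via a declining parent fraction
#' `f(t) = f_inf + (1 - f_inf) * exp(-lambda_pf * t)`.
#'
#' @param whole_blood A `continuous_curve` of whole-blood activity.
#' @param hct Hematocrit, fraction strictly in (0, 1) (default 0.42).
#' @param f_inf Asymptotic parent fraction in (0, 1] (default 0.5).
#' @param lambda_pf Parent-fraction decay rate in 1/min (default 0.03).
#' @return An `input_function` holding `whole_blood`, the corrected
#'   `plasma_parent` curve, and the correction parameters.
#' @export
apply_corrections <- function(whole_blood, hct = 0.42, f_inf = 0.5,
                              lambda_pf = 0.03) {
  stopifnot(inherits(whole_blood, "continuous_curve"))
  if (hct < 0 || hct >= 1) stop("hematocrit must lie in [0, 1)", call. = FALSE)
  stopifnot(f_inf > 0, f_inf <= 1, lambda_pf >= 0)
  t_min <- curve_times(whole_blood) / 60
  f <- f_inf + (1 - f_inf) * exp(-lambda_pf * t_min)
  plasma <- continuous_curve(whole_blood$values / (1 - hct) * f,
                             step = whole_blood$step)
  structure(list(whole_blood = whole_blood, plasma_parent = plasma,
                 hematocrit = hct, f_inf = f_inf, lambda_pf = lambda_pf),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(paste0("<input_function> hct %.2f, parent fraction %.2f + %.2f*",
                     "exp(-%g/min * t); plasma peak %.4g kBq/mL\n"),
              x$hematocrit, x$f_inf, 1 - x$f_inf, x$lambda_pf,
              max(x$plasma_parent$values)))
  invisible(x)
}

#' Parent fraction curve of an input function
#' @param input An `input_function`.
#' @param t_s Times in seconds.
#' @return Fraction of blood activity still attributable to parent tracer.
#' @export
parent_fraction <- function(input, t_s) {
  input$f_inf + (1 - input$f_inf) * exp(-input$lambda_pf * t_s / 60)
}

#' Pointwise mean of several continuous curves
#'
#' Builds a population-mean input curve on the common 1-second grid; curves
#' with other steps are linearly interpolated, and all are truncated to the
#' shortest span.
#'
#' @param curves Non-empty list of `continuous_curve` objects.
#' @param step Target grid step in seconds (default 1).
#' @return A `continuous_curve` of the pointwise arithmetic mean.
#' @export
population_mean_input <- function(curves, step = 1) {
  if (length(curves) == 0L) stop("need at least one curve", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "continuous_curve")))
  span <- min(vapply(curves, curve_end, numeric(1)))
  t <- seq(0, span, by = step)
  mat <- vapply(curves, function(cv) curve_at(cv, t), numeric(length(t)))
  continuous_curve(rowMeans(as.matrix(mat)), step = step)
}

#' Read / write the input-function CSV dialect (`t_s,value_kBq_per_mL`)
#' @param path File path.
#' @return `read_input_csv`: a `continuous_curve`.
#' @export
read_input_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "value_kBq_per_mL") %in% names(df))) {
    stop("input-function CSV must have columns t_s,value_kBq_per_mL", call. = FALSE)
  }
  steps <- diff(df$t_s)
  if (length(steps) < 1L || any(abs(steps - steps[1]) > 1e-9) || df$t_s[1] != 0) {
    stop("input-function CSV must be on a uniform grid starting at 0", call. = FALSE)
  }
  continuous_curve(df$value_kBq_per_mL, step = steps[1])
}

#' @param curve A `continuous_curve` to write.
#' @rdname read_input_csv
#' @export
write_input_csv <- function(curve, path) {
  stopifnot(inherits(curve, "continuous_curve"))
  utils::write.csv(data.frame(t_s = curve_times(curve),
                              value_kBq_per_mL = curve$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
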