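#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-residual AICc used to choose among compartment models fitted to
#' the same TAC: `n * ln(ss/n) + 2k + 2k(k+1)/(n - k - 1)` with `ss` the
#' (weighted) residual sum of squares, `n` the number of frames and `k` the
#' number of fitted parameters.
#'
#' @param ss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k Number of parameters.
#' @export
aicc <- function(ss, n, k) {
  stopifnot(is.numeric(ss), is.numeric(n), is.numeric(k))
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  if (ss <= 0) stop("AICc undefined: ss must be positive", call. = FALSE)
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

model_par_names <- function(model_id) {
  switch(model_id,
         "1T2k+VB" = c("K1", "k2", "VB"),
         "2T3k+VB" = c("K1", "k2", "k3", "VB"),
         "2T4k+VB" = c("K1", "k2", "k3", "k4", "VB"))
}

#' Default fit configuration
#'
#' Initialization, box bounds and multi-start jitters for the bounded
#' Levenberg-Marquardt fit. Rates are per-minute, `VB` a fraction.
#'
#' @param init Named numeric of starting values.
#' @param lower,upper Named numeric box bounds.
#' @param weights `"uniform"` (default) or `"duration"` (w_i = frame length).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param n_multistart Number of deterministic jittered restarts tried when
#'   the first start fails to converge.
#' @export
fit_options <- function(init = c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.01,
                                 VB = 0.05),
                        lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, VB = 0),
                        upper = c(K1 = 2, k2 = 2, k3 = 2, k4 = 2, VB = 0.5),
                        weights = c("uniform", "duration"),
                        max_iter = 100, n_multistart = 3) {
  weights <- match.arg(weights)
  list(init = init, lower = lower, upper = upper, weights = weights,
       max_iter = max_iter, n_multistart = n_multistart)
}

#' Fit a compartment model to a frame-sampled TAC
#'
#' Bounded Levenberg-Marquardt weighted nonlinear least squares. The model
#' curve is simulated on the input's fine grid and binned with the TAC's own
#' schedule before residuals are formed, so the fitted quantity has the same
#' frame-average semantics as the data. Non-convergence at the iteration cap
#' is reported via `converged = FALSE`, not an error; a few deterministic
#' jittered restarts are tried first.
#'
#' @param tac A `sampled_tac`, time-aligned to bolus arrival.
#' @param input An `input_function` or plasma `continuous_curve` covering the
#'   TAC's schedule.
#' @param model_id `"1T2k+VB"`, `"2T3k+VB"` or `"2T4k+VB"`.
#' @param options A [fit_options()] list.
#' @param vb_curve Optional separate blood curve for the VB term.
#' @return A `fit_result`: fitted `kinetic_params`, weighted `ss`, `n_frames`,
#'   `n_params`, `aicc`, `converged`, `n_iter`, and the fitted frame values.
#' @export
fit_model <- function(tac, input, model_id = "1T2k+VB", options = fit_options(),
                      vb_curve = NULL) {
  stopifnot(inherits(tac, "sampled_tac"))
  model_id <- match.arg(model_id, c("1T2k+VB", "2T3k+VB", "2T4k+VB"))
  pn <- model_par_names(model_id)
  k <- length(pn)
  n <- length(tac$values)
  if (n <= k) {
    stop(sprintf("underdetermined fit: %d frames for %d parameters", n, k),
         call. = FALSE)
  }
  cv <- resolve_input(input, vb_curve)
  dur <- schedule_duration(tac$schedule)
  n_grid <- round(dur / cv$cp$step) + 1L
  if (length(cv$cp$values) < n_grid) {
    stop("input curve does not cover the TAC schedule", call. = FALSE)
  }
  cp <- cv$cp$values[seq_len(n_grid)]
  cb <- cv$cb$values[seq_len(n_grid)]
  h <- cv$cp$step
  op <- bin_operator(n_grid, h, tac$schedule)
  w <- if (options$weights == "duration") tac$schedule$duration_s else rep(1, n)
  sw <- sqrt(w)

  par_to_kp <- function(p) {
    kinetic_params(model_id, K1 = p[["K1"]], k2 = p[["k2"]],
                   k3 = if ("k3" %in% pn) p[["k3"]] else 0,
                   k4 = if ("k4" %in% pn) p[["k4"]] else 0, VB = p[["VB"]])
  }
  resid_fn <- function(p) {
    model <- forward_model(par_to_kp(p), cp, cb, h)
    sw * (tac$values - apply_bin_operator(op, model))
  }

  starts <- list(options$init[pn])
  # deterministic multiplicative jitters keep restarts reproducible without
  # touching the session RNG (fits run inside seeded Monte Carlo streams)
  jit <- list(0.5, 2, c(1.5, 0.5, 1.5, 0.5, 1.5)[seq_len(k)])
  for (j in seq_len(options$n_multistart)) {
    s <- pmin(pmax(options$init[pn] * jit[[((j - 1) %% 3) + 1]],
                   options$lower[pn] + 1e-6), options$upper[pn])
    starts[[j + 1]] <- s
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = options$lower[pn], upper = options$upper[pn],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = options$max_iter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    conv <- fit$info %in% 1:3
    cand <- list(fit = fit, conv = conv, ss = fit$deviance)
    if (is.null(best) || (cand$conv && !best$conv) ||
        (cand$conv == best$conv && cand$ss < best$ss)) {
      best <- cand
    }
    if (best$conv) break
  }
  if (is.null(best)) stop("Levenberg-Marquardt failed on all starts", call. = FALSE)

  p <- best$fit$par
  ss <- best$ss
  kp <- par_to_kp(p)
  model_fit <- apply_bin_operator(op, forward_model(kp, cp, cb, h))
  structure(list(
    params = kp, model_id = model_id, ss = ss, n_frames = n, n_params = k,
    aicc = aicc(max(ss, .Machine$double.xmin), n, k),
    converged = best$conv, n_iter = best$fit$niter,
    fitted = model_fit, residuals = tac$values - model_fit,
    weights = w), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: ss=%.4g (n=%d frames), AICc=%.3f, %s in %d iter\n",
              x$model_id, x$ss, x$n_frames, x$aicc,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$params)
  invisible(x)
}

#' Select the best model by AICc
#'
#' Returns the fit with the lowest AICc; near-exact ties (|difference| <
#' 1e-9) are broken toward the model with fewer parameters (parsimony).
#'
#' @param fits Non-empty list of `fit_result` objects for the same TAC.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("need at least one fit", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  best <- which(a < min(a) + 1e-9)
  fits[[best[which.min(k[best])]]]
}

#' Fit all three compartment models and pick the AICc-best one
#' @inheritParams fit_model
#' @return List with `fits` (all three `fit_result`s) and `selected`.
#' @export
fit_all_models <- function(tac, input, options = fit_options(), vb_curve = NULL) {
  ids <- c("1T2k+VB", "2T3k+VB", "2T4k+VB")
  fits <- lapply(ids, function(m) fit_model(tac, input, m, options, vb_curve))
  names(fits) <- ids
  list(fits = fits, selected = select_model(fits))
}

#' Logan graphical analysis
#'
#' Estimates the total distribution volume Vt as the slope of the late linear
#' segment of the Logan plot: ordinary least squares of
#' `int_0^t C dtau / C(t)` against `int_0^t Cp dtau / C(t)` over frame
#' midpoints with `t >= t_star`. The plasma curve is binned with the TAC's
#' own schedule so both cumulative integrals share the same frame quadrature.
#'
#' @param tac A `sampled_tac` with positive values after `t_star`.
#' @param plasma Plasma input: `input_function` or `continuous_curve`.
#' @param t_star Start of the linear segment in seconds (default 600), or
#'   `"auto"` to pick the largest tail window whose worst relative deviation
#'   from the line is at most `auto_tol`.
#' @param auto_tol Maximum relative deviation for `t_star = "auto"` (0.10).
#' @return A `logan_result`: `vt` (mL/ccm), `intercept` (min), `t_star`,
#'   `n_points`, `r2`.
#' @export
logan_vt <- function(tac, plasma, t_star = 600, auto_tol = 0.10) {
  stopifnot(inherits(tac, "sampled_tac"))
  cp <- if (inherits(plasma, "input_function")) plasma$plasma_parent else plasma
  stopifnot(inherits(cp, "continuous_curve"))
  sched <- tac$schedule
  cp_b <- bin_curve(crop_curve(cp, schedule_duration(sched)), sched)$values
  dt <- sched$duration_s
  # cumulative integral at frame midpoints: full preceding frames + half of own
  cum_mid <- function(v) cumsum(v * dt) - v * dt / 2
  int_t <- cum_mid(tac$values)
  int_p <- cum_mid(cp_b)

  fit_window <- function(ts) {
    use <- which(sched$mid_s >= ts)
    if (length(use) < 3L) stop("fewer than 3 Logan points after t_star", call. = FALSE)
    ct <- tac$values[use]
    if (any(ct <= 0)) stop("non-positive TAC values in the Logan window", call. = FALSE)
    x <- int_p[use] / ct
    y <- int_t[use] / ct
    fit <- stats::lm.fit(cbind(1, x), y)
    yhat <- fit$fitted.values
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (!is.finite(r2)) r2 <- 1 # zero-variance y: perfectly flat, treat as exact
    list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
         r2 = max(0, min(1, r2)), n = length(use), t_star = ts,
         maxdev = max(abs(fit$residuals) / pmax(abs(yhat), .Machine$double.eps)))
  }

  if (identical(t_star, "auto")) {
    res <- NULL
    for (ts in sched$mid_s[seq_len(max(1, nrow(sched) - 2))]) {
      cand <- fit_window(ts)
      if (cand$maxdev <= auto_tol) { res <- cand; break }
    }
    if (is.null(res)) stop("no tail window meets the Logan linearity tolerance",
                           call. = FALSE)
  } else {
    res <- fit_window(t_star)
  }
  structure(list(vt = unname(res$slope), intercept = unname(res$intercept) / 60,
                 t_star = res$t_star, n_points = res$n, r2 = res$r2),
            class = "logan_result")
}

#' @export
print.logan_result <- function(x, ...) {
  cat(sprintf("<logan_result> Vt=%.4g mL/ccm, intercept=%.4g min, t*=%g s, %d points, R2=%.4f\n",
              x$vt, x$intercept, x$t_star, x$n_points, x$r2))
  invisible(x)
}
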