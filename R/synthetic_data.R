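#' Configuration of the synthetic lesion cohort
#'
#' Defines the distributions of a fully synthetic glioma cohort standing in
#' for a dynamic FDOPA PET study: patients with 1-3 biopsied lesions each,
#' lesion kinetic parameters scattered around cohort means, per-patient
#' image-derived input functions, and paired static uptake values (SUVmax at
#' 20 and 35 min) whose tumor-to-brain ratio declines from 20 to 35 min in
#' every lesion.
#'
#' Kinetic parameters are lognormal (K1, k2) and logit-normal (VB) around the
#' cohort medians, with a shared per-patient random effect controlling the
#' intraclass correlation of lesions within a patient.
#'
#' @param n_patients,n_lesions Cohort size (defaults 14 patients, 33 lesions).
#' @param k1_median Median K1, mL/ccm/min (0.161).
#' @param k2_median Median k2, 1/min (0.087).
#' @param vb_median Median blood volume fraction (0.084).
#' @param k1_sdlog,k2_sdlog Log-scale sd of K1 and k2.
#' @param vb_sdlogit Logit-scale sd of VB.
#' @param icc Intraclass correlation of log-parameters within a patient.
#' @param tbr20_mean Mean tumor-to-brain SUVmax ratio at 20 min (1.4).
#' @param tbr_decline_mean,tbr_decline_shape Mean and gamma shape of the
#'   per-lesion log-decline of TBRmax from 20 to 35 min; the default mean
#'   `log(1.4/1.2)` gives mean TBRmax about 1.2 at 35 min, always below the
#'   20-min value within each lesion.
#' @param dose_per_kg Injected activity, MBq per kg body weight (2).
#' @param weight_mean,weight_sd Body weight distribution, kg (75 +/- 12).
#' @param hct_mean,hct_sd Hematocrit distribution.
#' @param seed Integer seed making the cohort reproducible.
#' @export
cohort_config <- function(n_patients = 14, n_lesions = 33,
                          k1_median = 0.161, k2_median = 0.087,
                          vb_median = 0.084,
                          k1_sdlog = 0.5, k2_sdlog = 0.4, vb_sdlogit = 0.5,
                          icc = 0.3,
                          tbr20_mean = 1.4,
                          tbr_decline_mean = log(1.4 / 1.2),
                          tbr_decline_shape = 4,
                          dose_per_kg = 2, weight_mean = 75, weight_sd = 12,
                          hct_mean = 0.42, hct_sd = 0.03,
                          seed = 1) {
  stopifnot(n_patients >= 1, n_lesions >= n_patients,
            k1_median > 0, k2_median > 0, vb_median > 0, vb_median < 1,
            k1_sdlog >= 0, k2_sdlog >= 0, vb_sdlogit >= 0,
            icc >= 0, icc < 1, tbr20_mean > 0, tbr_decline_mean > 0,
            tbr_decline_shape > 0, dose_per_kg > 0, weight_mean > 0)
  as.list(environment())
}

#' Standardized uptake value
#'
#' `SUV = tissue concentration / (injected dose / body weight)` with
#' concentration in kBq/mL, dose in MBq and weight in kg; 1 mL of tissue is
#' taken as 1 g, so the normalizing term is `dose * 1000 kBq / (weight * 1000
#' g)`.
#'
#' @param conc Tissue concentration, kBq/mL (> 0).
#' @param injected_dose Injected activity, MBq (> 0).
#' @param weight Body weight, kg (> 0).
#' @export
compute_suv <- function(conc, injected_dose, weight) {
  if (any(conc <= 0) || any(injected_dose <= 0) || any(weight <= 0)) {
    stop("concentration, dose and weight must all be positive", call. = FALSE)
  }
  conc / (injected_dose * 1000 / (weight * 1000))
}

# spread n_lesions over n_patients as evenly as possible (1-3 each for the
# default 33/14), then shuffle which patients carry the extra lesion
assign_lesions <- function(n_lesions, n_patients) {
  base <- n_lesions %/% n_patients
  extra <- n_lesions %% n_patients
  sizes <- rep(base, n_patients)
  if (extra > 0) sizes[sample.int(n_patients, extra)] <- base + 1
  rep(seq_len(n_patients), times = sizes)
}

rtrunc_norm <- function(n, mean, sd, lo) {
  v <- stats::rnorm(n, mean, sd)
  pmax(v, lo)
}

#' Generate a synthetic dynamic-PET lesion cohort
#'
#' Draws patients (weight, injected dose, hematocrit, a jittered bolus input
#' function) and lesions (kinetic parameters with a within-patient random
#' effect), forward-simulates each lesion's 1T2k+VB TAC from its patient's
#' metabolite- and hematocrit-corrected input function, bins it into
#' `schedule`, and derives paired static uptake values:
#' tumor SUVmax from the late-window tissue concentration (so static uptake
#' is downstream of the lesion's kinetics), a contralateral-cortex reference
#' scaled such that the cohort-mean TBRmax at 20 min matches the configured
#' value, and a per-lesion positive decline making TBRmax at 35 min lower in
#' every lesion. Logan Vt is computed from each noiseless TAC.
#'
#' @param cfg A [cohort_config()].
#' @param schedule Frame schedule (spec string or `frame_schedule`) for the
#'   binned TACs; default the optimal 8x15,2x30,2x60,3x300 scheme.
#' @param noise_c Optional Poisson-noise scaling factor; `NULL` (default)
#'   leaves the TACs noiseless.
#' @return A `pet_cohort` list: `lesions` data frame (one row per lesion with
#'   true parameters, SUV/TBR values and Logan `vt`), `tacs` (named list of
#'   `sampled_tac`), `inputs` (per-patient `input_function`), `patients`
#'   data frame, `schedule`, `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            schedule = "8x15,2x30,2x60,3x300",
                            noise_c = NULL) {
  if (is.character(schedule)) schedule <- make_schedule(schedule)
  set.seed(cfg$seed)
  np <- cfg$n_patients
  nl <- cfg$n_lesions

  patient_id <- assign_lesions(nl, np)
  weight <- rtrunc_norm(np, cfg$weight_mean, cfg$weight_sd, 40)
  dose <- cfg$dose_per_kg * weight
  hct <- pmin(pmax(stats::rnorm(np, cfg$hct_mean, cfg$hct_sd), 0.3), 0.55)

  inputs <- vector("list", np)
  for (p in seq_len(np)) {
    wb <- synth_bolus(amplitude = 30 * stats::rlnorm(1, 0, 0.15),
                      t_peak = rtrunc_norm(1, 35, 5, 20))
    inputs[[p]] <- apply_corrections(wb, hct = hct[p])
  }
  names(inputs) <- sprintf("P%02d", seq_len(np))

  # shared patient effect + lesion effect on the log / logit scale
  draw_re <- function(sdtot, n_pat, pat_idx) {
    sp <- sdtot * sqrt(cfg$icc)
    sl <- sdtot * sqrt(1 - cfg$icc)
    stats::rnorm(n_pat, 0, sp)[pat_idx] + stats::rnorm(length(pat_idx), 0, sl)
  }
  K1 <- cfg$k1_median * exp(draw_re(cfg$k1_sdlog, np, patient_id))
  k2 <- cfg$k2_median * exp(draw_re(cfg$k2_sdlog, np, patient_id))
  vb_logit <- log(cfg$vb_median / (1 - cfg$vb_median)) +
    draw_re(cfg$vb_sdlogit, np, patient_id)
  VB <- 1 / (1 + exp(-vb_logit))

  dur <- schedule_duration(schedule)
  late <- c(dur - 300, dur) # last 5 min of the 20-min acquisition
  late_mean <- function(curve) {
    idx <- which(curve_times(curve) >= late[1] & curve_times(curve) <= late[2])
    mean(curve$values[idx])
  }

  # reference cortex concentration anchored so a cohort-mean lesion on the
  # population-mean input lands at the configured mean TBRmax(20)
  mean_input <- population_mean_input(lapply(inputs, `[[`, "plasma_parent"))
  mean_par <- kinetic_params("1T2k+VB", K1 = cfg$k1_median, k2 = cfg$k2_median,
                             VB = cfg$vb_median)
  ref_conc0 <- late_mean(simulate_1t2k_vb(mean_par, mean_input, dur)) /
    cfg$tbr20_mean

  tacs <- vector("list", nl)
  conc20 <- numeric(nl)
  vt <- numeric(nl)
  # uniform 30-s binning of the noiseless curve gives the Logan regression
  # enough late points regardless of the analysis schedule requested
  logan_sched <- make_schedule(sprintf("%dx30", dur %/% 30))
  for (l in seq_len(nl)) {
    par <- kinetic_params("1T2k+VB", K1 = K1[l], k2 = k2[l], VB = VB[l])
    curve <- simulate_1t2k_vb(par, inputs[[patient_id[l]]], dur)
    tac <- bin_curve(curve, schedule)
    conc20[l] <- late_mean(curve)
    vt[l] <- logan_vt(bin_curve(curve, logan_sched), inputs[[patient_id[l]]],
                      t_star = 600)$vt
    if (!is.null(noise_c)) tac <- add_poisson_frame_noise(tac, noise_c)
    tacs[[l]] <- tac
  }
  names(tacs) <- sprintf("L%02d", seq_len(nl))

  peak_fac <- stats::rlnorm(nl, log(1.2), 0.1)    # SUVmax voxel vs VOI mean
  ref_mult <- stats::rlnorm(np, 0, 0.15)          # per-patient cortex level
  ref_peak <- stats::rlnorm(nl, log(1.2), 0.05)
  ratio_ref <- stats::runif(nl, 0.95, 1.05)       # cortex 35/20 ratio
  decline <- stats::rgamma(nl, shape = cfg$tbr_decline_shape,
                           rate = cfg$tbr_decline_shape / cfg$tbr_decline_mean)
  ratio_tum <- ratio_ref * exp(-decline)          # tumor declines faster

  suv20 <- compute_suv(conc20 * peak_fac, dose[patient_id], weight[patient_id])
  ref20 <- compute_suv(ref_conc0 * ref_mult[patient_id] * ref_peak,
                       dose[patient_id], weight[patient_id])
  # re-anchor the cortex reference so the cohort-mean TBRmax(20) equals the
  # configured level exactly (lognormal means exceed the medians the raw
  # anchor was built from)
  ref20 <- ref20 * mean(suv20 / ref20) / cfg$tbr20_mean
  suv35 <- suv20 * ratio_tum
  ref35 <- ref20 * ratio_ref

  lesions <- data.frame(
    lesion_id = names(tacs),
    patient_id = names(inputs)[patient_id],
    K1 = K1, k2 = k2, VB = VB, dv = K1 / k2, vt = vt,
    suvmax_20 = suv20, suvmax_35 = suv35,
    ref_suvmax_20 = ref20, ref_suvmax_35 = ref35,
    tbrmax_20 = suv20 / ref20, tbrmax_35 = suv35 / ref35,
    row.names = NULL)
  patients <- data.frame(patient_id = names(inputs), weight_kg = weight,
                         dose_MBq = dose, hematocrit = hct, row.names = NULL)
  structure(list(lesions = lesions, tacs = tacs, inputs = inputs,
                 patients = patients, schedule = schedule, config = cfg),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d lesions in %d patients on %s (seed %d)\n",
              nrow(x$lesions), nrow(x$patients), attr(x$schedule, "label"),
              x$config$seed))
  cat(sprintf("  median K1 %.3f mL/ccm/min, mean TBRmax 20min %.2f / 35min %.2f\n",
              stats::median(x$lesions$K1), mean(x$lesions$tbrmax_20),
              mean(x$lesions$tbrmax_35)))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `cohort.csv` (lesion table), `patients.csv`, one TAC CSV per lesion,
#' one input-function CSV per patient, and `manifest.json` recording the seed
#' and configuration.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 10) else col)
    df
  }
  utils::write.csv(num(cohort$lesions), file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num(cohort$patients), file.path(dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  for (l in names(cohort$tacs)) {
    write_tac_csv(cohort$tacs[[l]], file.path(dir, sprintf("tac_%s.csv", l)))
  }
  for (p in names(cohort$inputs)) {
    write_input_csv(cohort$inputs[[p]]$plasma_parent,
                    file.path(dir, sprintf("input_%s.csv", p)))
  }
  manifest <- list(seed = cohort$config$seed,
                   schedule = attr(cohort$schedule, "label"),
                   n_patients = cohort$config$n_patients,
                   n_lesions = cohort$config$n_lesions,
                   config = cohort$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
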