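# dynpet

Kinetic analysis of dynamic PET time-activity curves (TACs) and
optimization of the time-frame binning scheme, built around amino-acid
tracer (FDOPA) imaging of glioma.

Dynamic PET quantification fits a compartment model to a lesion's TAC
together with an arterial plasma input function. Before any of that can
happen, list-mode data must be binned into time frames — and the frame
schedule is itself an analysis parameter: coarse early frames blur the bolus
passage, very short frames are individually noisy. `dynpet` provides the
whole chain for studying this at the volume-of-interest level on synthetic
data:

* frame-schedule parsing (`"8x15,2x30,2x60,3x300"`-style specs), binning of
  continuous curves into frames, bolus-arrival detection;
* synthetic bolus-shaped input functions with hematocrit and metabolite
  (parent-fraction) corrections;
* forward simulation of the reversible single-tissue model with blood
  volume, `C(t) = VB·C_IDIF(t) + (1−VB)·K1·e^(−k2·t) ⊗ C_IDIF(t)`
  (1T2k+VB), and the two-tissue 2T3k+VB / 2T4k+VB models;
* bounded Levenberg–Marquardt fitting, small-sample Akaike (AICc) model
  selection, and Logan graphical analysis (total distribution volume Vt);
* a frame-wise Poisson noise model, `c·(Pois(C)−C)/√dt`, with Monte Carlo
  comparison of candidate schedules against a target K1 and calibration of
  the noise scale to a target K1 dispersion;
* a seeded synthetic lesion cohort (patients, lesions, input functions,
  TACs, paired 20-/35-min SUVmax and tumor-to-brain ratios);
* paired Wilcoxon signed-rank tests (exact under ties), Benjamini–Hochberg
  FDR adjustment, and Spearman correlation matrices.

Rates are per minute (K1 in mL/ccm/min), curves in kBq/mL on a 1-second
grid, frame times in seconds.

## Worked example

```r
library(dynpet)

input <- apply_corrections(synth_bolus(amplitude = 30, t_peak = 35), hct = 0.42)
truth <- kinetic_params("1T2k+VB", K1 = 0.161, k2 = 0.087, VB = 0.084)
sched <- make_schedule("8x15,2x30,2x60,3x300")
tac   <- bin_curve(simulate_1t2k_vb(truth, input, 1200), sched)

set.seed(1)
noisy <- add_poisson_frame_noise(tac, c_factor = 1.9)
fit_model(noisy, input, "1T2k+VB")
#> <fit_result> 1T2k+VB: ss=17.76 (n=15 frames), AICc=10.713, converged in 4 iter
#> <kinetic_params> 1T2k+VB: K1=0.1714 mL/ccm/min, k2=0.09841/min, VB=0.0907
```

One noisy realization at the Table-scale noise level recovers K1 to ~6%.
Comparing two binning schemes over 128 paired noise realizations:

```r
compare_schedules(c("8x15,2x30,2x60,3x300", "4x45,3x90,5x150"),
                  truth, input, c_factor = 1.9, n_realizations = 128, seed = 42)
#> <schedule_comparison> target K1 = 0.161 mL/ccm/min
#>               schedule mean_k1   sd_k1 ci95_low ci95_high  abs_bias n_converged
#> 1 8x15-2x30-2x60-3x300   0.161 0.01286   0.1587    0.1632 2.932e-05         128
#> 2      4x45-3x90-5x150   0.162 0.01030   0.1603    0.1638 1.040e-03         128
#>   p_vs_best p_adj_vs_best
#> 1        NA            NA
#> 2      0.39          0.39
```

`mean_k1` is the mean fitted K1 across realizations, `abs_bias` its distance
from the target, and `p_vs_best` the paired Wilcoxon test of each schedule's
K1 draws against the top-ranked schedule's (BH-adjusted in
`p_adj_vs_best`). Here the finely-sampled schedule is essentially unbiased;
see the vignette for why schedule-dependent bias is intrinsically small when
the fitter uses the same frame-average forward model as the simulator.

A full synthetic cohort with paired static uptake values:

```r
co <- generate_cohort(cohort_config(seed = 1))
co
#> <pet_cohort> 33 lesions in 14 patients on 8x15-2x30-2x60-3x300 (seed 1)
#>   median K1 0.169 mL/ccm/min, mean TBRmax 20min 1.40 / 35min 1.20
cohort_tests(co)$tbr_test
#>                   name statistic      p_value p_adjusted  n               method
#> 1 wilcoxon_signed_rank       561 5.644724e-07         NA 33 normal approximation
```

The 20-minute tumor-to-brain ratio exceeds the 35-minute one in every lesion
(statistic 561 = all 33 positive ranks), so the paired test rejects
decisively.

## Layout

* `R/` — schedules & binning, input functions, kinetic models, fitting &
  Logan, Monte Carlo, synthetic cohort, statistics.
* `tests/testthat/` — unit and property tests per module, including
  closed-form convolution oracles, an adaptive ODE cross-check, exhaustive
  Wilcoxon enumeration oracles, and end-to-end acceptance checks.
* `vignettes/frame-binning-kinetics.Rmd` — the methods vignette: models,
  discretization, noise calibration, cohort generator design, and what the
  synthetic experiments do and do not demonstrate.
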