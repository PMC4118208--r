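# icgpv

Plasma volume (PV) estimation from indocyanine green (ICG) dilution, with a
physiologically based model of why the traditional analysis is biased and a
corrected back-extrapolation protocol.

## The problem

After an intravenous ICG bolus, plasma concentrations over 2–5 minutes are
well described by a mono-exponential decay `A·exp(-k·t)` driven by hepatic
clearance, and PV is estimated by indicator dilution:

    PV (L) = dose (mg) / ICG(t_a) (mg/L)

with `ICG(t_a)` the fitted curve back-extrapolated to time `t_a`. The
traditional choice `t_a = 0` pretends the dye was mixed and being cleared
from the instant of injection. In reality the bolus takes on the order of a
minute to reach the liver and about two minutes to mix, so `ICG(0)`
overestimates the theoretical initial concentration and PV is
underestimated — by about 17% at moderate clearance and about 30% at
near-complete hepatic extraction. An overestimate of `+p%` in `ICG_0` maps
exactly to a PV error of `-100·p/(100+p)%`.

`icgpv` is for clinical pharmacologists and physiologists who run the ICG
dilution protocol, and for modellers who want the error structure of
back-extrapolation estimators. It provides:

* a 3-loop circulation model — hepatic (30% of flow), non-hepatic (65%),
  and the injection vein's loop (5%) — each a periodic domain carrying a
  1-D advection–diffusion equation, coupled by a localized heart-mixing
  term `β·h(x)·(m − ·)` and drained by a localized hepatic clearance term
  `α·f(x)·u`, solved with a Fourier spectral method (exact integrating
  factor for transport, RK4 for the local terms);
* the sampling/fitting pipeline: 30-second sampling from 2 to 5 min at
  `x = π` of the non-hepatic loop, log-linear mono-exponential fitting,
  back-extrapolation, and the dilution formula;
* calibration operators (well-mixed-by-2-minutes mixing calibration;
  clearance-to-decay-rate inversion) and the minimax search for the
  back-extrapolation time that is accurate across clearance rates
  (`t_a ≈ 1.1` min here; `t_a = 1` min is the practical recommendation and
  the package default);
* a clinical mode: per-subject timed concentrations in CSV, per-subject
  fits and PV at any `t_a`, cohort summaries, and a seeded synthetic-cohort
  generator emulating the study design (0.25 mg/kg dosing, 7 samples,
  multiplicative assay noise).

## Worked example

Simulate a clinically representative clearance (`alpha = 29` gives a fitted
decay rate of about 0.24/min), run the measurement protocol, and compare the
traditional and proposed estimators:

```r
library(icgpv)

sim     <- simulate_icg(icg_params(alpha = 29))
samples <- sample_trace(sim)          # 7 samples, 2-5 min, v(t, pi)
fit     <- fit_monoexp(samples)
fit
#> <monoexp_fit> A = 1.32004, k = 0.23892 /min, r^2 = 0.9979 (n = 7)

estimate_pv(dose = 1, fit, t_a = c(0, 1))
#> # A tibble: 2 × 5
#>    dose   t_a icg_at_ta    pv pv_per_kg
#>   <dbl> <dbl>     <dbl> <dbl>     <dbl>
#> 1     1     0      1.32 0.758        NA
#> 2     1     1      1.04 0.962        NA
```

Concentrations are normalized so the true initial concentration and system
volume are both 1: back-extrapolating to `t = 0` inflates `ICG_0` by 32%
and recovers only 76% of the true volume, while `t_a = 1` min recovers 96%.

The clinical mode works from long-format CSV
(`subject_id,weight_kg,dose_mg,time_min,conc_mg_per_L`); a small synthetic
example ships with the package:

```r
path   <- system.file("extdata", "synthetic_subjects.csv", package = "icgpv")
cohort <- compute_cohort_pv(read_subjects(path), t_a_list = c(0, 1))
glance(cohort)
#> # A tibble: 2 × 6
#>     t_a     n pv_l_mean pv_l_sd pv_ml_per_kg_mean pv_ml_per_kg_sd
#>   <dbl> <int>     <dbl>   <dbl>             <dbl>           <dbl>
#> 1     0     4      2.42   0.536              26.2            5.81
#> 2     1     4      3.35   0.625              36.4            7.18
```

The traditional `t_a = 0` column sits well below commonly reported PV
values (~40 mL/kg); the proposed `t_a = 1` column does not. Per-subject
estimates are in `tidy(cohort)`, and `PV(t_a=1) = PV(t_a=0)·exp(k)` holds
exactly for each subject. `autoplot()` methods exist for simulations, error
curves, sensitivity curves and cohorts; `vignettes/icg-plasma-volume.Rmd`
documents the model, calibration and design choices.

A thin command-line front end with `simulate`, `estimate-pv`, `error-curve`,
`find-ta`, `sensitivity`, `synth` and `cohort` subcommands lives at
`inst/cli/icgpv.R` and accepts a flat key-value config file for all model
parameters.

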