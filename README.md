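# fillfrac

Single-beat estimation of the left-ventricular dead-space volume, and the
filling fraction it unlocks as a non-invasive preload metric.

## The problem

In a preload-recruitable stroke-work (PRSW) model of heart function, stroke
work is linear in end-diastolic volume,

    SW = M_W · (EDV − V_W),

with slope `M_W` (a contractility index, work per unit volume) and volume
intercept `V_W`, the *dead-space volume*: the residual cavity volume of a
fully contracted ventricle, below which no work can be performed. Dividing
through by EDV gives a three-factor decomposition of ejection fraction,

    EF = FF · M_W / MAP,      FF = (EDV − AMV) / EDV,

where the **filling fraction** FF is a dimensionless, BSA-index-free preload
metric and the physiologic ceiling on EF (AMV, the absolute minimum volume,
is the estimate of `V_W`). Classically `V_W` requires preload manipulation
and extrapolation — impractical or contraindicated in the critically ill.
This package implements a **single-beat** estimator instead:

1. the rate-corrected circumferential shortening velocity and end-systolic
   wall stress give a contractility Z-score
   `Z_C = (V_CFC + 0.0044·ESS − 1.23)/0.06` and gain
   `G_C = C₁Z_C + √((C₁Z_C)² + 1)`;
2. a linear end-systolic stress–stretch law, `ESS = G_C·M_N·(λ_ES − 1)` with
   `M_N ≈ 500 g/cm²`, yields the end-systolic mid-wall stretch and hence the
   fully contracted mid-wall perimeter `PMW_AM = PMW_ES / λ_ES`;
3. the near-cubic volume–perimeter law `LVV = a·PMW³ − b`, fitted exactly
   through the measured ED and ES states, is extrapolated to `PMW_AM`:
   `AMV = a·PMW_AM³ − b`.

A truncated prolate-ellipsoid shell generator (incompressible myocardium,
constant shape, closed-form inflation) provides the in-silico verification:
10,000 uniformly sampled synthetic hearts whose true dead-space volume is
known by construction.

Intended users: cardiovascular modellers and echocardiography researchers
evaluating preload metrics; the estimator consumes standard per-beat echo
measurements (LVID and wall thickness at ED/ES, volumes, wall stress, RR
interval, MAP).

## Worked example

```r
library(fillfrac)
b <- echo_beat(lvid_ed = 4.8, h_ed = 0.9, lvid_es = 3.2, h_es = 1.4,
               edv = 120, esv = 50, ess = 60, rr = 0.8, map = 92,
               vcfc_override = 0.99)
fit <- amv_single_beat(b)
summary(fit)
```

```
Single-beat dead-space volume estimate
  AMV = 29.03 mL  (ESV 50 mL, EDV 120 mL)
  PMW_AM = 13.01 cm (lambda_ES 1.1108, G_C 1.0832, Z_C +0.400)
  EF = 0.583, FF = 0.758 (fill volume 90.97 mL)
  M_W = 70.8 mmHg (96.25 g/cm^2) at MAP 92 mmHg
```

Reading: this beat's shortening velocity sits 0.4 SD above the mean-normal
stress–velocity line, so contractility gain is 1.08; the stress–stretch law
puts end-systolic stretch at 1.11, the mid-wall perimeter of the fully
contracted ventricle at 13.0 cm, and the extrapolated dead-space volume at
29 mL — well below the 50 mL end-systolic volume, as it must be. Of the
120 mL end-diastolic volume, 76% is usable fill volume (FF = 0.76, the
ceiling on this heart's EF of 0.58), and the implied PRSW slope is
71 mmHg (96 g/cm²).

The in-silico verification:

```r
res <- run_experiment(sampling_plan())   # 10,000 hearts, < 1 s
agreement_stats(res)
```

```
Dead-space volume agreement over 10000 hearts
  bias +1.0391 mL, RMSE 1.2525 mL, max |rel err| 0.3248
  v_w ~ amv_hat: slope 0.99351, intercept -0.8767 mL, R^2 0.996877
```

Estimated and true dead-space volumes track the identity line (slope 0.99,
R² 0.997) with ~1 mL bias; the largest relative errors arise in small,
thick-walled hearts, where the cubic law's thin-wall approximation is
weakest. `export_figures_data()` writes plot-ready trajectory and scatter
tables; `takeuchi_fixture()` reproduces the published group-mean comparison
in which ventricular dilation triples the dead space and drags FF from 0.80
to 0.53 — capping EF at the heart-failure threshold before contractility is
even considered.

A command-line wrapper is installed at
`system.file("cli", "fillfrac.R", package = "fillfrac")` with `estimate`,
`metrics` and `simulate` subcommands over CSV/JSON files.

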