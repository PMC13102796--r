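---
title: "Single-beat estimation of left-ventricular dead-space volume: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-beat estimation of left-ventricular dead-space volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fillfrac)
```

## The model

The preload-recruitable stroke-work (PRSW) view of ventricular function
makes stroke work linear in end-diastolic volume,
$SW = M_W (EDV - V_W)$, with slope $M_W$ (contractility, work per unit
volume) and intercept $V_W$, the dead-space volume below which the
ventricle performs no work. Writing $SW = MAP \cdot SV$ and dividing by
$EDV$ yields

$$EF = FF \cdot \frac{M_W}{MAP}, \qquad FF = \frac{EDV - AMV}{EDV},$$

an exact three-factor separation of ejection fraction into preload
(filling fraction $FF$), contractility and afterload. $FF$ is
dimensionless, invariant to body-surface-area indexing, and the ceiling on
$EF$: whenever $M_W \le MAP$ in common units, $EF \le FF$.

Everything therefore hinges on estimating $AMV$ (the dead-space volume)
from a single beat. The estimator rests on two approximate linearities:

1. **Stress–stretch at end systole.** Myocyte stress at a static
   end-systolic contraction is taken linear in stretch with x-intercept at
   stretch 1: $ESS = G_C M_N (\lambda_{ES} - 1)$, where
   $\lambda_{ES} = PMW_{ES}/PMW_{AM}$ is the mid-wall circumferential
   stretch relative to the fully contracted (absolute-minimum, AM) state.
   With $\lambda_{ES} \approx 1.12$ and $ESS \approx 60$ g/cm² in normal
   hearts, the normal slope is $M_N \approx 500$ g/cm². Contractility
   enters through a gain $G_C = C_1 Z_C + \sqrt{(C_1 Z_C)^2 + 1}$ (equal
   to 1 at normal contractility; reciprocal under sign flip of the
   Z-score), where $Z_C$ is the number of vertical standard deviations the
   beat's rate-corrected circumferential shortening velocity lies above
   the mean-normal stress–velocity line,
   $Z_C = (V_{CFC} + 0.0044\,ESS - 1.23)/0.06$.
2. **Volume–perimeter.** For ellipsoidal shells whose axial dimension
   varies in proportion to the hoop dimension, cavity volume is nearly
   cubic in mid-wall perimeter: $LVV = a\,PMW^3 - b$, with $b$ the muscle
   volume inside the mid-wall shell. $a$ and $b$ are fitted *exactly*
   through the measured ED and ES states (two-point interpolation), which
   absorbs patient-specific thickness, aspect and motion factors without
   modelling them.

Combining the two: $PMW_{AM} = PMW_{ES}/\lambda_{ES}$ and
$AMV = a\,PMW_{AM}^3 - b$. Because $PMW_{AM} \le PMW_{ES}$ and $a > 0$,
the estimate never exceeds the end-systolic volume for non-negative
stress — a structural safety property the tests assert cohort-wide.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `m_n` | 500 | g/cm² | normal end-systolic stress–stretch slope |
| `c_1` | 0.2 | — | Z-score-to-gain shape constant (a coarse literature estimate; exposed everywhere) |
| pressure conversion | 1.35951 | g/cm² per mmHg | mercury density 13.5951 g/cm³ over a 1 mm column |

Contractility and afterload are fundamentally the same unit (work per
volume = pressure); the package tags pressures with their unit and refuses
mixed-unit arithmetic rather than converting silently.

The shortening velocity $V_{CFC}$ is computed from perimeters and the RR
interval by default, with an explicit `vcfc_override` field for
literature-scale values. The override matters in practice: the
normal-population relation (intercept 1.23 s⁻¹) is calibrated to clinical
velocity measurements, while the raw geometric shortening fraction of a
shell model is an order of magnitude smaller (~0.2 s⁻¹), which would push
$Z_C$ to absurdly negative values. Synthetic beats in the test-suite
therefore supply a consistent override, as the field intends.

## The synthetic-heart generator

The verification cohort models the LV as a truncated prolate-ellipsoid
shell of uniform radial thickness with incompressible myocardium and
constant shape. With cavity semi-axes $A = kB$, thickness $H$, truncation
ratio $L$ (0 = half shell, 1 = complete ellipsoid; total height
$T = A(1+L)$):

$$LVV = \tfrac{2}{3}\pi A B^2 (1 + L + L^2 - L^3), \qquad
  V_M = \tfrac{2}{3}\pi A H (1 + L + L^2 - L^3)(H + 2B), \qquad
  PMW = \pi(2B + H).$$

Two modelling notes, made deliberately and documented rather than hidden:

* The wall-volume expression equals `cavity_volume(A, B+H, L) −
  cavity_volume(A, B, L)` identically — the "uniform thickness" is added
  radially only, not along the long axis. We follow the equations, which
  define the model.
* The shape polynomial $(1 + L + L^2 - L^3)$ coincides with the exact
  ellipsoid-cap integral $(1 + \tfrac32 L - \tfrac12 L^3)$ only at $L = 0$
  and $L = 1$ (about 5% below it at $L = 0.375$). It is the model's shape
  family, not a quadrature; self-consistency (cavity, wall, perimeter all
  from the same family) is what the estimator relies on, and the tests
  check the exact limits plus the algebraic wall-volume identity.

**Inflation is closed-form.** Fixing $PMW = \lambda\,PMW_{AM}$ collapses
$H + 2B$ to $P = PMW/\pi$, so conservation of $V_M = C\,B\,(P-2B)\,P$ with
$C = \tfrac23 \pi k (1 + L + L^2 - L^3)$ is quadratic in $B$ with roots
$B$ and $H/2$; we always take the larger root, i.e. enforce $H < 2B$,
which the sampling ranges guarantee at the AM state
($H_{AM} \le 2.0 < 2.6 \le 2B_{AM}$) and inflation preserves (it raises
$B$ and lowers $H$). A bisection solver exists in the test helpers purely
as an independent oracle. $\lambda = 1$ returns the AM state itself: the
fixed point is honoured exactly rather than through the root formula,
whose floating-point rounding would reproduce $B_{AM}$ only to machine
precision.

**Sampling plan** (uniform, independent; no physiological correlations):
10,000 hearts, $LVID_{AM} \in [2.6, 4.6]$ cm, $H_{AM} \in [1.0, 2.0]$ cm,
$k \in [1, 2]$, $L \in [0, 0.375]$, $\lambda_{ES} \in [1.06, 1.18]$,
$\lambda_{ED} \in [1.24, 1.36]$. The source text also mentions $L$ up to
$3/4$ in its geometric preliminaries; we default to the range stated for
the verification experiment and leave the bound configurable. The default
seed (20260302) is recorded in every exported summary; identical plan and
seed give byte-identical CSVs.

Two experiment modes: `true_pmw_am` (default) uses each heart's known AM
perimeter, isolating the cubic-law extrapolation; `ess_pathway`
synthesises $ESS = G_C M_N (\lambda_{ES} - 1)$ and lets the estimator
invert it, exercising the stress chain end to end. With the same gain on
both sides the inversion is exact and the modes agree to 1e−9 relative.

## What the verification does and does not show

```{r cohort}
res <- run_experiment(sampling_plan())
agreement_stats(res)
```

Along every heart's inflation trajectory, cavity volume is collinear with
$PMW^3$ to $R^2 > 0.999$ over 50 stretch points — the cubic law is an
excellent within-heart approximation. Extrapolating it roughly one
stretch-decade below end systole accumulates error where walls are
relatively thick: the largest relative errors (up to ~0.32 at this plan)
occur in the smallest, thickest-walled hearts, and $|$relative
error$|$ correlates ~0.93 with $H_{AM}/LVID_{AM}$. In absolute terms the
agreement is tight (bias ≈ +1.0 mL, RMSE ≈ 1.25 mL, regression of truth on
estimate with slope 0.994, $R^2$ 0.997). The regression thresholds frozen
in the test suite come from a reference run of this same experiment — the
source publication shows the agreement graphically without printing a
statistic — and exist to prevent regressions, not to certify accuracy.

Passing these tests shows the estimator recovers the dead space of
*ellipsoidal shells with exactly linear stress–stretch behaviour and
noise-free measurements*. Real hearts add measurement noise, regional
heterogeneity, non-ellipsoidal remodelling and dynamic effects the static
shell cannot represent; none of that is probed here, which is why the
generator's role is verification of the mathematics, not clinical
validation.

## Numerical choices

* Conservation of wall volume under inflation is asserted at 1e−9
  relative; state equalities (fixed point, perimeter ratios) at 1e−12.
* The two-point fit refuses perimeter pairs whose cubes differ by less
  than 1e−9 relative (degenerate beats raise an error; they do not return
  infinities).
* Negative or supra-ESV dead-space estimates are returned raw with
  diagnostic flags (`NEGATIVE_AMV`, `AMV_ABOVE_ESV`): the estimator is a
  measurement and downstream users decide.
* Cohort computations are fully vectorised (the closed-form root makes
  per-heart cost trivial); the 10,000-heart experiment with per-heart
  linearity diagnostics runs in well under a second, so the test suite
  exercises it at full size.
* Exported CSVs round to 6 significant digits for stable diffs; JSON
  summaries keep full precision.

## The group-mean worked example

```{r fixture}
takeuchi_fixture()
```

Between the control and dilated heart-failure groups the dead space
roughly triples (ratio 310%) while EDV grows far less (134%), so FF falls
from 0.80 to 0.53 — a 33% relative reduction that lowers the EF ceiling to
the heart-failure threshold by preload alone. In both groups EF sits about
14 and 13 percentage points below FF, consistent with afterload never
being zero. The published account also apportions the EF reduction ~60/40
between FF and contractility without stating the apportionment formula;
the package documents this note but computes no such split.

## Known limitations

The estimator inherits the PRSW model's linearity assumptions; the shell
model is static, axisymmetric, uniformly (radially) thick and
shape-constant through the cycle; end-systolic wall stress is an input
(its echocardiographic measurement is out of scope); and volumes are
inputs, not derived from linear dimensions. Thick-walled small ventricles
are the estimator's weakest regime, as the verification quantifies.
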