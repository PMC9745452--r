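---
title: "Methods: growth-curve kinetics of RF lesion formation under LI guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve kinetics of RF lesion formation under LI guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionkinetics)
```

## The problem

Radiofrequency ablation creates a lesion whose size grows with delivery
time, but not linearly: direct resistive heating at the electrode–tissue
interface acts within seconds, while conductive heating deepens the
lesion slowly thereafter. The local impedance (LI) measured between the
catheter's distal tip and a ring electrode drops as tissue heats, making
the *LI drop* a real-time surrogate for lesion formation. The practical
question this package quantifies: at which delivery time does lesion
growth effectively saturate, and how faithfully does the LI drop track
lesion depth, diameter and volume?

## Model and assumptions

Every saturating response $Y$ (LI drop, Ω; lesion depth or maximum
diameter, mm) is modelled against delivery time $t$ (s) as a one-phase
association curve with zero intercept:

$$Y(t) = Y_{\max}\,\bigl(1 - e^{-kt}\bigr),\qquad Y_{\max} > 0,\; k > 0.$$

Assumptions worth stating:

- **Zero intercept.** No lesion and no LI drop at $t = 0$. This removes
  one parameter and is physically forced.
- **Cross-sectional endpoints.** Each duration is a *different* lesion
  (the tissue is destroyed by measurement), so replicates at all
  durations are pooled as independent points, unweighted. No
  mixed-effects structure is attempted; replicate-level random effects
  cannot be identified from one observation per lesion.
- **Monotone saturating mean.** Responses that grow linearly over the
  observed window — lesion volume over 5–60 s behaves this way, being a
  product of dimensions that saturate at different rates — use an
  ordinary linear fit (`fit_linear()`) instead.

The growth rate $dY/dt = Y_{\max} k e^{-kt}$ peaks at $t = 0$ and decays
exponentially. The **time to 90% decay** of the peak rate is the time at
which $dY/dt$ first equals 10% of its maximum:

$$t_{90} = \ln(10)/k \approx 2.303/k,$$

independent of the plateau. Times before $t_{90}$ form the *rapidly
increasing phase*, at or after it the *slowly increasing phase*
(`phase_partition()`; a time exactly at the boundary is classified slow —
a closed boundary on the slow side, chosen so that "ablating up to
$t_{90}$" is the longest ablation still entirely in the fast phase).

Lesion volume from the four calliper axes uses the two-frustum
approximation $V = \tfrac{\pi}{6}(a b^2 + c d^2/2)$, with the halved term
applying to $c\,d^2$ only (literal operator precedence of the printed
formula). Only $c \le a$ is enforced as a geometric invariant; $d > b$ is
permitted since a shallow lesion's surface diameter can exceed its
widest subsurface section.

## Fitting: profiled least squares

For fixed $k$, the least-squares plateau is available in closed form,
$\hat Y_{\max}(k) = \sum w_i y_i g_i / \sum w_i g_i^2$ with
$g_i = 1 - e^{-k t_i}$, so the residual sum of squares is a function of
$k$ alone. `fit_one_phase()` minimises it by a coarse log-spaced scan
(60 nodes over $k \in [10^{-6}, 10]$ 1/s) followed by bounded Brent
search and a tight polish pass. Compared with a 2-D trust-region solver
this cannot fail with singular gradients on noiseless or
perfectly-saturated data, and recovers generating parameters to better
than $10^{-6}$ relative on noiseless input (property-tested).

**Degeneracy policy.** A fit whose rate lands within 1% of either search
bound — near-linear data pushing $k \to 0$, or data saturating faster
than the time grid resolves pushing $k$ up — or with a non-positive
plateau is flagged `degenerate`, and `time_to_90_decay()` refuses to run
on it rather than report a misleading time. All-zero responses are
flagged without fitting.

$R^2 = 1 - SS_{res}/SS_{tot}$ is computed on the fitted points and
clamped to $[0, 1]$; for zero-variance data it is defined as 0.

## The decay statistic, three ways

1. **Closed form** (default): $t_{90} = \ln(10)/k$, peak rate
   $Y_{\max} k$ at $t=0$.
2. **Numeric grid**: the analytic derivative is sampled every 0.05 s
   from 0 to 1.5× the last fitted time; the first grid time at which it
   is ≤ 10% of the sampled peak is reported (ties count as crossed). The
   two routes agree within one grid step — an invariant the test suite
   checks across $k \in [0.02, 0.5]$. When the crossing lies beyond the
   initial horizon (slow rates: $k = 0.02$ puts $t_{90}$ at 115 s), the
   horizon doubles up to a 10⁴ s cap; for a one-phase fit the crossing
   always exists, so this terminates.
3. **Empirical, from a continuous LI trace**: centered moving-average
   smoothing (default window 1 s, a CLI-exposed parameter — the source
   protocol does not describe smoothing), centered finite differences,
   then the same peak/threshold rule. Near the trace edges the smoothing
   window shrinks *symmetrically*, keeping each smoothed sample centred
   on its own time; an asymmetric edge window would bias the derivative
   peak late by half a window. On noiseless sampled curves the estimator
   converges to $\ln(10)/k$ as the sampling rate grows (checked at 1, 10
   and 100 Hz; error 1.1 s, 0.10 s, 0.014 s for $k = 0.0491$). It is
   noise-sensitive: at 10 Hz with noise SD comparable to the per-second
   LI gain, the 1 s window is too short and the peak estimate inflates —
   widen `smoothing_window` for noisy traces. A measured trace may peak
   after $t=0$ (catheter settling); `t90` is reported on the trace's own
   time axis unless `from_peak = TRUE`.

## Threshold crossings

`time_to_threshold()` inverts the fitted mean:
$t = -\ln(1 - y^*/Y_{\max})/k$ for the one-phase model, raising an
"unreachable threshold" error (carrying the plateau) when
$y^* \ge Y_{\max}$; for linear fits $t = (y^* - b)/\text{slope}$,
including the intercept so that the round-trip contract
`predict(fit, time_to_threshold(fit, y)) == y` holds to $10^{-9}$
relative in both models. The default depth threshold is 4 mm — the usual
upper bound on atrial wall thickness, hence the transmurality target for
pulmonary-vein isolation.

## Inference

- **Trend in steam-pop incidence** (`cochran_armitage_trend()`): the
  standard Cochran–Armitage statistic
  $Z = \sum s_i(x_i - n_i\bar p)\,/\,\sqrt{\bar p(1-\bar p)[\sum n_i s_i^2 - (\sum n_i s_i)^2/N]}$
  with the actual delivery times as scores (times are the natural dose
  metric; $Z$ is invariant to positive affine score maps, so any common
  rescaling is equivalent). Asymptotic two-sided normal p by default;
  `exact = TRUE` enumerates the conditional permutation null
  (multivariate hypergeometric given the pooled success count), and
  `n_perm` draws a Monte-Carlo permutation p — the enumeration serves as
  the independent oracle for the Monte-Carlo route in the tests. Under a
  null simulation (6 groups of 10, p = 0.5, 2000 tables) the asymptotic
  test's type-I error sits near 0.05 (asserted within [0.03, 0.07]).
- **LI drop vs lesion size**: Pearson correlation with t-distributed
  two-sided p (delegated to `stats::cor.test`).
- **40 W vs 50 W at matched time/contact force**
  (`compare_power_groups()`): Welch's unequal-variance comparison,
  two-sided, α = 0.05, *no multiplicity correction* — matching the
  per-point asterisk-marking practice of dose–response figures; the
  source never names its test, so this documented default is a package
  choice. Whether per-time tests or an omnibus comparison was intended
  is unknowable from the source; we record the ambiguity rather than
  guess further. Cells present in one power group only (the 5 s point
  exists only in the 50 W design) are skipped and logged.

## The synthetic world

`simulate_experiment()` emulates the factorial ex vivo design exactly:
40 W at {10, 20, 30, 40, 50, 60} s, 50 W at {5, 10, 20, 30, 40, 50,
60} s, contact forces {10, 30, 50} g, n = 10 lesions per cell. Truth
parameters come from the bundled calibration
(`inst/extdata/calibrated_truths.json`, exposed via
`calibration_table()`):

- **Rate constants** invert published decay times, $k = \ln(10)/t_{90}$
  (`truth_from_decay_time()`).
- **Depth plateaus** are solved per setting from the published 4 mm
  crossing anchors, $Y_{\max} = 4/(1 - e^{-k t_4})$ — both numbers are
  printed for all six settings, so depth needs no assumptions.
- **LI-drop plateau 120 Ω and diameter plateau 8 mm** are *assumed*
  constants (no plateaus are printed); they are marked
  `"provenance": "assumed"` in the calibration file. The decay statistic
  is plateau-free, so these choices affect only noise-to-signal ratios.
- **Noise**: LI drop CV 10% (multiplicative — endpoint LI drops scale
  with their mean), depth/diameter SD 0.3 mm (sub-millimetre calliper
  repeatability). Chosen once as a realistic bench world; with them the
  default-config one-phase fits land in the R² band 0.85–0.98 that
  matched published per-setting fits, which is logged (not asserted) by
  the acceptance suite. Negative draws are resampled, not clipped, so
  there is no point mass at zero.
- **Steam pops**: Bernoulli with logistic probability in time,
  40 W: $\text{logit}^{-1}(-6 + 0.06\,t)$,
  50 W: $\text{logit}^{-1}(-5 + 0.08\,t)$ — synthetic values (the
  incidence figure is an image), chosen so pops are rare and
  late-concentrated at 40 W (~0.2% at 10 s, ~8% at 60 s) and earlier
  and more frequent at 50 W (~1.5% at 10 s, ~31% at 60 s), with the
  50 W curve dominating everywhere.
- **Geometry coupling** $c = 0.5a$, $d = 0.8b$ is a synthetic-only
  convention so volume is computable from generated records; real
  lesions decouple these axes.

**Seeding.** Each (power, CF, time) cell draws from its own stream,
seeded by a stated integer hash of the master seed and the cell labels
(kept below $2^{31}$). Extending the design with new cells therefore
never perturbs existing cells — verified by a regression test.

What a green test establishes: the estimator pipeline recovers the
generating kinetics without material bias at the design's n, and the
full analysis round-trips the calibrating values exactly in the
noiseless limit. What it does not establish: anything about real tissue
— the generator has no bioheat physics, no catheter-angle or irrigation
effects, no inter-slice heterogeneity, and its noise model is a stated
convention.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| $k$ search bounds | $[10^{-6}, 10]$ 1/s | decay times from 0.23 s to 320 h; generous both ways |
| degeneracy margin | 1% of bound | flags boundary solutions before they corrupt $t_{90}$ |
| grid step / horizon | 0.05 s / 1.5× last time, doubling to $10^4$ s | one-step agreement with the closed form; slow rates cross late |
| tie at 10% of peak | counts as crossed | first-crossing rule, closed on the crossing side |
| phase boundary tie | slow phase | "ablate up to $t_{90}$" stays entirely fast |
| smoothing window | 1.0 s, symmetric edge shrink | unbiased edge derivative; parameter exposed |
| trend scores | delivery times | natural dose metric; affine-invariant anyway |
| volume `/2` grouping | on $c d^2$ only | literal precedence of the printed formula |

## Known limitations

- The decay statistic for lesion responses is necessarily taken on the
  *fitted* curve — lesion size is cross-sectional, so its derivative is
  not observable per lesion; this is the only computable reading.
- Published figures report decay times to 0.1 s with internal
  inconsistencies at that digit between table and text for one setting
  (30.8 vs 30.7 s); the bundled calibration follows the running text.
- The empirical trace estimator degrades with noise at the default 1 s
  window (see above); it is meant for clean bench traces or wider
  windows.
- No mixed-effects, heteroscedastic or bi-exponential modelling; no
  multiplicity-adjusted test families; no bioheat simulation. All are
  out of scope by design.
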