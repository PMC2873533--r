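---
title: "Shape-based kinetic outlier detection: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based kinetic outlier detection: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodpcr)
```

## The model

An amplification trace is modelled by the five-parameter Richards function

$$F(x) = F_b + F_{max}\,\bigl(1 + e^{-(x-c)/b}\bigr)^{-d},$$

with background $F_b$, plateau $F_{max}$ above background, scale $b$ (cycles),
location $c$ (cycles) and asymmetry exponent $d$. The curve rises
monotonically from $F_b$ to $F_b + F_{max}$; $d = 1$ is the symmetric
logistic, $d \to \infty$ approaches Gompertz-like kinetics. The inflection
point has closed-form geometry:

$$x_f = c + b\ln d, \qquad
  Y_f = F_{max}(1 + 1/d)^{-d}, \qquad
  m = \frac{F_{max}}{b}(1 + 1/d)^{-(d+1)},$$

and the normalized asymmetry is
$\mathrm{Asym} = (F_{max} - 2Y_f)/F_{max} = 1 - 2(1+1/d)^{-d}$.

**Convention: $Y_f$ excludes the background.** Whether the inflection
ordinate should include $F_b$ is a genuine choice; we exclude it so that the
symmetry identity $d = 1 \Leftrightarrow 2Y_f = F_{max} \Leftrightarrow
\mathrm{Asym} = 0$ holds *exactly*, and so that all three fingerprint
coordinates scale identically under a change of fluorescence units
(multiplying a trace by $k$ multiplies $F_{max}$, $Y_f$ and $m$ by $k$ and
leaves $d$ and Asym invariant — a property the test suite checks).

The fingerprint $(F_{max}, Y_f, m)$ is the test vector. Asym is reported
descriptively but deliberately **not** included in the test: the outlier
statistic uses exactly three coordinates and three degrees of freedom, and
Asym is a deterministic function of $d$ alone, so adding it would mostly
re-weight information already in $Y_f/F_{max}$.

## The two outlier tests

**SOD.** Standard-curve runs define the reference: $\mu$ and $\Sigma$ are the
sample mean and covariance (denominator $n-1$) of their fingerprints. A run
with fingerprint $y$ scores $d^2 = (y-\mu)'\Sigma^{-1}(y-\mu)$, computed via
Cholesky backsolve (the explicit inverse is never formed; tests compare
against a cofactor-inverse oracle to $10^{-10}$). Under multivariate
normality $d^2$ is asymptotically $\chi^2_3$; a run is flagged when
$d^2 > \chi^2_{3,0.95} = 7.81$. Critical values are always computed from the
distribution function, never hard-coded. No small-sample $F$ correction is
applied — the asymptotic test is the method as defined — but
`build_reference()` warns when the reference has fewer than 30 runs, where
the asymptotic calibration is rough. No iterative trimming of the reference
is performed: runs the reference itself flags stay in $\mu, \Sigma$.

**KOD.** Per-run efficiency is $10^{\text{slope}}$ of the ordinary
regression of $\log_{10} F$ on cycle inside the *window of linearity*, and
$z = (E - \mu_E)/\sigma_E$ against the standards' efficiencies
($\sigma_E$ with denominator $n-1$); $z^2 > \chi^2_{1,0.95} = 3.84$ flags
the run.

**Degenerate runs.** A trace the Richards model cannot fit — flat, never
reaching 10 % of the reference plateau (configurable), optimizer failure, or
an estimate pinned at a box bound — is by definition shape-aberrant: it is
reported as a SOD outlier with $d^2 = \infty$ and a reason code, and
excluded from the reference if it is a standard. Symmetrically, a run whose
efficiency window cannot be formed is reported as a KOD outlier with reason
`efficiency_undetermined`. A method cannot certify a run it cannot evaluate.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| fluorescence threshold | 0.4 | fluorescence | conventional fit-point setting for this signal scale |
| SOD / KOD alpha | 0.05 | — | reproduces the 7.81 / 3.84 / 1.96 thresholds |
| window width | 4–6 | cycles | window-of-linearity convention of log-linear efficiency tools |
| window band | 1 %–80 % of plateau | — | keeps readings above noise and below plateau saturation |
| plateau screen | 10 % of reference plateau | — | separates "no amplification" from "aberrant amplification" |
| fit bounds | $b \in [0.1, 20]$, $d \in [0.05, 20]$, $F_{max} \le 10\times$range, $c \in [1, 2C]$ | cycles / fluorescence | keeps the exponent well-conditioned; a bound hit marks non-convergence |

## Numerical choices

* **Fitting.** Levenberg–Marquardt through `minpack.lm::nls.lm` on the raw
  residual function (the `nls`-object wrapper fails on exactly noiseless
  traces, which the test suite uses for parameter-recovery checks). Starting
  values: $F_b$ from the first five readings, $F_{max}$ from the observed
  range, $c$ at the half-maximum crossing, $b = 2$, $d = 1$ — inside the
  basin of attraction for any sigmoid trace. Tolerances `ftol = ptol =
  1e-15`, max 500 iterations. Noiseless traces are recovered to better than
  $10^{-4}$ relative error, and refitting a fit's own prediction is
  idempotent to $10^{-6}$.
* **Overflow.** The exponent argument is clipped at ±700 and
  $(1+e^z)^{-d}$ is evaluated as $\exp(-d\,\mathrm{log1p}(e^z))$ with a
  large-$z$ shortcut, so the model is total on the whole real line.
* **Ct interpolation.** The fit-point Ct interpolates *linearly* between the
  cycles flanking the first upward threshold crossing. Log-linear
  interpolation would be marginally less biased in the exponential phase,
  but the bias is below 0.1 cycles for realistic slopes and the linear rule
  is what instrument software effectively reports.
* **Window anchoring.** Among eligible windows the one maximizing $R^2$ of
  $\log_{10}F$ vs cycle wins (ties: wider, then earlier). When the trace
  crosses the quantification threshold, candidate windows must contain the
  crossing, with one cycle of grace below the window start: the 1 %-of-
  plateau noise floor can sit fractionally *above* the 0.4 threshold, which
  would otherwise exclude every window that respects the floor.
* **Truth band.** `Log(Nob/Nexp)` over the standards is summarized as mean
  ± 1.96·SD (normal-theory band; an empirical quantile was the alternative,
  but at n = 72 the normal band is more stable and matches the normality
  the K-S diagnostic checks). Bounds are inclusive: a residual exactly on
  the bound is not an outlier (measure-zero convention).
* **K-S convention.** `ks_normality()` reports $Z = \sqrt{n}\,D$ with the
  asymptotic Kolmogorov p-value — the legacy statistics-package convention,
  chosen because reference values on that scale round-trip correctly
  (e.g. $Z = 0.99$ at $n = 72$ gives $p \approx 0.28$). It is not a
  Lilliefors-corrected test; with estimated mean and SD it is slightly
  conservative.

## The simulator: what it emulates, and what it does not

`simulate_plate()` reproduces the *structure* of a dilution-series
calibration experiment: 6 concentrations × 12 replicates spanning
$3.14\times10^7$ down to $3.14\times10^2$ copies, 40 cycles, overall
efficiency 1.9. Shape parameters $(F_{max}, b, d)$ are drawn lognormally
(positivity by construction) with means $(46.41, 2.0, 1.2)$ and CVs
$(0.13, 0.10, 0.08)$ — plateau mean and dispersion on the scale of published
SYBR-green calibration data, $b$ and $d$ giving an early-phase growth factor
$e^{d/b} \approx 1.8$ consistent with that efficiency scale. Only the
location $c = c_{top} + \Delta\log_{10}N/\log_{10}E$ depends on input
amount, so shape is concentration-independent by construction. Read noise is
additive homoscedastic Gaussian (SD 0.05).

Inhibition of strength $s \in [0,1]$ multiplies $F_{max}$ by $(1-0.6s)$ and
$b$ by $(1+s)$ (plateau and slope suppression), and for the asymmetric kind
also $d$ by $(1+2s)$ (tannic-acid/IgG-like kinetic distortion); the
symmetric kind leaves $d$ untouched (quercitin-like). The coefficients are
qualitative dose-response knobs chosen once to produce monotone suppression
and asymmetry growth; they are exposed in the config and are not claims
about inhibitor chemistry.

**Known gaps between simulator and real data.** (i) Real replicate wells
share well-to-well correlation (master mix, plate position) that the
i.i.d. draws ignore. (ii) Real fluorescence noise is heteroscedastic,
growing with signal. (iii) Because $b$ and $d$ vary independently of $c$,
the threshold-crossing cycle inherits shape noise: the simulated
`Log(Nob/Nexp)` band (σ ≈ 0.28) is much wider than a well-behaved
instrument's (σ ≈ 0.04). Consequently the simulator is a *structural*
testbed — passing tests demonstrate correct machinery, calibration and the
SOD-vs-KOD sensitivity ordering, not instrument-level quantification
precision. (iv) Window-of-linearity efficiencies carry downward bias and
higher dispersion than plateau-normalized tools report; the KOD reference
absorbs this because test and reference runs share the bias.

## Calibration and evaluation design

Null calibration is estimated by Monte Carlo: 10 independent reference sets
of $n = 72$ fingerprints, each tested with 2000 fresh null draws from the
same trivariate normal (20 000 draws total). Averaging over reference sets
matters: at $n = 72$ the *conditional* flag rate given one reference set
varies from ~3 % to ~15 % because the asymptotic threshold ignores
reference-estimation noise, while the marginal rate is a stable ~6–7 %.
The same protocol calibrates KOD on $N(1.88, 0.02^2)$ efficiencies.

The SOD-vs-KOD comparison runs 20 simulated studies (seeds derived from one
master seed), each 72 standards plus 4 replicates at each inhibition
strength $\{0.6, \ldots, 1.0\}$ spiked at $3.5\times10^4$ copies;
sensitivity and specificity are scored against the `Log(Nob/Nexp)` truth
band per stratum. These problem sizes keep the full suite and the
acceptance script in the tens of seconds on one core while leaving the
stochastic margins wide.

## Limitations

* Developed for intercalating-dye (SYBR-green-like) signals; probe
  chemistries change the shape family and would need re-validation.
* The asymptotic $\chi^2_3$ threshold is anti-conservative for small
  reference sets (see above); below ~30 standards, treat flags near the
  threshold with caution.
* No robust covariance estimation: a contaminated reference inflates
  $\Sigma$ and hides outliers. Standards should be curated (the pipeline
  reports which standards the tests flag).
* The window-of-linearity implementation is a self-contained reimplementation
  of the convention, not a port of any instrument tool; absolute efficiency
  values carry method variance even when relative (z-scored) comparisons are
  sound.
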