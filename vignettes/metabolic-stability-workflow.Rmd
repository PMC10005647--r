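---
title: "Methods: weighted calibration, validation statistics, and substrate-depletion clearance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted calibration, validation statistics, and substrate-depletion clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstabr)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and why their defaults
are what they are, and the places where a design choice was genuinely open.

## The measurement model

An LC-MS/MS assay quantifies an analyte against a co-extracted internal
standard (IS). The primary observable per injection is the response ratio
$y = A_{\mathrm{analyte}} / A_{\mathrm{IS}}$, assumed linear in
concentration over the working range:

$$ y = a\,x + b + \varepsilon, \qquad \mathrm{SD}(\varepsilon) \propto x .$$

Peak-area noise is positive and roughly proportional to signal, which is
why `fit_calibration()` defaults to $1/x$ weighting: weighted least squares
with $w_i = 1/x_i$ equalises the relative influence of low and high
standards. Weights $1$ and $1/x^2$ are available for assays whose noise
structure differs. Two quantities are deliberately pinned down because the
guideline formulas consume them:

* the **weighted coefficient of determination**, computed on weighted
  residuals, $r^2 = 1 - \sum w_i e_i^2 / \sum w_i (y_i - \bar y_w)^2$ with
  $\bar y_w$ the weighted mean — the unweighted $r^2$ of a weighted fit is
  not a meaningful diagnostic;
* the **SD of the intercept**, taken from the standard weighted-regression
  covariance $\hat\sigma^2 (X^\top W X)^{-1}$, which feeds
  $\mathrm{LOD} = 3.3\,\mathrm{SD}_b/a$ and
  $\mathrm{LOQ} = 10\,\mathrm{SD}_b/a$, so $\mathrm{LOQ}/\mathrm{LOD} =
  10/3.3$ identically.

Back-calculation inverts the line, $x = (y-b)/a$. Negative back-calculated
concentrations are flagged and reported, never clipped or dropped: silently
truncating at zero biases every downstream mean.

## Validation statistics

The validation suite is the usual bioanalytical set, each a one-line
estimator applied to replicate groups:
$\mathrm{RSD}\% = 100\,s/\bar x$ (sample SD, $n-1$ divisor — the divisor is
a convention choice; replicate-based estimation argues for the unbiased
variant), $\mathrm{RE}\% = 100(\bar x - x_{\mathrm{nom}})/x_{\mathrm{nom}}$,
recovery $= 100\,\overline{B}/\overline{A}$ (matrix-extracted over neat),
matrix effect $= 100\,\overline{\mathrm{set1}}/\overline{\mathrm{set2}}$,
and the IS-normalized matrix effect, the ratio of analyte to IS matrix
effects. Note the identity recovery% $=$ RE% $+ 100$ when the reference is
the nominal level; the precision/accuracy grid carries both.

Acceptance thresholds (±15% accuracy, ±20% at the LLOQ, ≥75% of calibration
levels passing, carryover below 20% of the LLOQ response and 5% of the IS
response, ±15% stability) are the bioanalytical guideline's conventions.
They are configuration defaults, not constants, because laboratories adapt
them per program. Boundary values pass (≤), matching how the limits are
phrased.

The intraday scope of `precision_accuracy_table()` uses the first day
unless a day is named: "same day" is otherwise ambiguous when a table spans
several days, and the first day is the only choice that is well-defined for
every input.

## Substrate depletion and intrinsic clearance

The metabolic-stability analysis implements the in vitro $t_{1/2}$
(substrate-depletion) approach. With substrate concentration well below
$K_m$, parent loss in a microsomal incubation is first order, so percent
remaining relative to time zero,

$$ X(t) = 100 \cdot \frac{C(t)}{C(0)}, $$

decays as $\ln X = \ln X_0 - k\,t$ over the early phase. Real incubations
flatten at later times (NADPH depletion, enzyme inactivation), so the
linear fit must be restricted. `select_linear_range()` automates the
by-inspection choice reproducibly: among contiguous prefixes anchored at
$t=0$ with at least `min_points = 4` points, it keeps the longest whose
ln-linear $r^2 \ge$ `r2_min = 0.99`. Anchoring at zero matters — the
definition of $X$ makes $t=0$ the reference point, and dropping early
points would redefine the curve. When no prefix qualifies, the best prefix
is used with a warning rather than an error, because a flagged estimate is
more useful than none; a manual range override is honored verbatim for
analysts who prefer the classical visual choice.

From the fitted rate, $t_{1/2} = \ln 2 / k$, and intrinsic clearance is
scaled with physiological factors:

$$ \mathrm{CL_{int}} = \frac{0.693}{t_{1/2}}
   \cdot \frac{\text{mL incubation}}{\text{mg microsomes}}
   \cdot \frac{\text{mg microsomal protein}}{\text{g liver}}
   \cdot \frac{\text{g liver}}{\text{kg b.w.}} $$

Defaults: 1 mL/mg (a 1 mg protein/mL incubation), 45 mg protein per g
liver, 26 g liver per kg body weight — the standard human scaling values.
The numerator is the conventional rounded constant 0.693 by default, with
`decay_constant = log(2)` available; the two differ by 0.02%, well below
replicate noise, but the rounded constant is what the field's worked
examples print. Both unit systems are returned, linked by the exact
identity $\mathrm{CL_{int}}^{(\mathrm{mL/min/kg})} =
\mathrm{CL_{int}}^{(\mu\mathrm{L/min/mg})} \cdot 45 \cdot 26 / 1000$ at the
default factors. Classification uses the McNaney-style bands, low below
8.6 and high above 47 µL/min/mg, with boundaries assigned to the
intermediate class (a tie at a band edge should not produce the extreme
call); the bands are configurable and echoed in reports.

Replicates at a time point are averaged before $X$ is formed. Depletion
summaries in this field report mean-per-time curves, and averaging first
makes $X(0) = 100$ exact; per-replicate fits can be run by subsetting the
time course if a variance estimate of $k$ is wanted.

## Composite site lability

For in silico triage the package aggregates per-site metabolic lability
rate constants into the composite site lability score
$\mathrm{CSL} = k_{\mathrm{total}}/(k_{\mathrm{total}} + k_w)$, where
$k_{\mathrm{total}}$ sums the site constants and $k_w$ is the
water-formation rate constant. The score is bounded in $[0,1]$, monotone
in each site constant, and invariant to merging sites (only the sum
enters). The per-site contribution table divides each $k_i$ by the same
denominator, so contributions sum exactly to the CSL. The upstream
regioselectivity predictor that produces per-site constants is proprietary
and out of scope; the package consumes its exported table
(`atom_label, k`).

## What the simulators emulate

`sim_config()` encodes the study conditions the package is tested under:

* **Calibration**: 8 levels at 1, 15, 50, 150, 300, 500, 1500, 3000 ng/mL;
  response line with slope 1.7298 and intercept 3.62941 (a published
  response equation used as a convenient default — synthetic sets carry
  their own ground truth, so the specific values are not load-bearing);
  multiplicative noise with CV 3%, typical of a well-behaved MRM assay.
* **QC**: the LLQC/LQC/MQC/HQC design at 1/3/900/2400 ng/mL, 6 replicates
  over 3 days, with optional accuracy bias and per-day shift.
* **Depletion**: 10 time points (0–70 min), 3 replicates, time-0
  concentration 584 ng/mL, decay toward a plateau at 26% remaining, CV 5%
  at the concentration level.
* **Chromatograms**: Gaussian peaks on a uniform grid with constant
  baseline and additive noise, integrated by the trapezoid rule above a
  local linear baseline — enough structure to test the area pipeline, not
  a physical model of chromatography.

Noise is multiplicative log-normal parameterized by CV with mean exactly 1
(meanlog $= -\sigma^2_{\log}/2$): peak areas are positive and
heteroscedastic, which is also the premise of the $1/x$ weighting. A master
seed fans out to fixed per-table substreams so regenerating one table never
perturbs another, and a fixed seed reproduces files byte for byte.

The depletion generator uses a plateau model,
$X(t) = p + (100-p)e^{-r t}$, because measured curves flatten; a pure
exponential is the $p = 0$ special case. The operational rate constant —
what the pipeline's ln-linear fit over the 0–30 min window estimates — is
not the mechanistic $r$ when $p > 0$. The generator therefore solves for
the $r$ whose noiseless ln-linear fit over the configured window has slope
exactly `k_true` (the operational slope is non-monotone in $r$, so the
solver brackets the first crossing), and reports `k_true` as the ground
truth `k_eff`. This makes "the fit recovers the truth" exact at zero noise
and well-defined under noise. A consequence worth knowing: with a plateau
at 26%, no mechanistic rate can produce an operational 0–30 min slope much
above ~0.045/min; the generator raises a clear error rather than silently
extrapolating.

What passing tests do **not** show about real data: the simulators draw
independent log-normal errors, so they cannot exhibit run order drift,
carryover between injections, matrix lot differences, or correlated
replicate errors. The validation statistics are estimators, not guarantees;
on real data their values depend on those untestable structures.

## Numerical choices and degenerate inputs

* Fits use QR least squares (`stats::lm`); tests verify agreement with an
  explicit normal-equations solution to 1e-10 relative.
* $r^2$ values for the decay fits are computed from residual sums directly,
  so numerically perfect fits (zero-noise simulations) are handled without
  special cases.
* A constant time course yields a zero slope and raises a structured
  "no measurable decay" error at the half-life step (rates below 1e-12/min
  are treated as zero — that threshold is ~9 orders of magnitude below any
  measurable depletion rate).
* Non-positive percent-remaining values make the logarithm undefined; the
  error names the offending time point.
* Back-calculated negatives are flagged, not altered.
* Degenerate calibration designs (one level, identical levels) error before
  fitting.
* All validation-statistic denominators (nominal, neat mean, IS response)
  are checked for zero with classed validation errors.

## Problem sizes used in the test suite

The suite runs Monte-Carlo checks at 100–200 seeds for parameter-recovery
properties (calibration slope within 1% over 200 seeds; median relative
error of the recovered depletion rate below 5% at the 10-point/5%-CV
design over 200 seeds; matrix effect and recovery means over 100 seeds) and
exhaustive small-case checks elsewhere. These sizes give Monte-Carlo
standard errors comfortably below the asserted margins.

## Known limitations

* Only linear calibration is implemented; quadratic or 4PL response models
  are out of scope.
* The depletion model assumes first-order loss below $K_m$;
  Michaelis–Menten kinetics and in vivo extrapolation beyond the intrinsic
  clearance scaling are out of scope.
* The MRM metadata block is provenance only; the package never interprets
  instrument parameters numerically, and vendor raw files are not parsed.
* Incurred-sample reanalysis, dilution integrity, and whole-blood stability
  are not part of the validation suite.
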