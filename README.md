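# metstabr

Quantitative bioanalysis and metabolic-stability analysis for LC-MS/MS drug
metabolism work. The package is aimed at DMPK/bioanalytical scientists who
have peak areas or back-calculated concentrations in hand and need the
numbers a method-validation report and a microsomal stability study are
built from:

* **Weighted calibration** — weighted least squares of the analyte/IS
  response ratio on nominal concentration (weights 1, 1/x, or 1/x²),
  back-calculation of unknowns, LOD/LOQ from the intercept SD
  (LOD = 3.3·SD_b/a, LOQ = 10·SD_b/a), and per-level acceptance checks.
* **FDA-style validation statistics** — precision (RSD% = 100·SD/mean),
  accuracy (RE% = 100·(mean − nominal)/nominal), extraction recovery
  (100·mean(B)/mean(A)), matrix effect (100·mean(set1)/mean(set2)),
  IS-normalized matrix effect, carryover limits, and stability windows.
* **Substrate-depletion metabolic stability** — the in vitro t½ approach:
  percent remaining X(t) = 100·C(t)/C(0), automatic selection of the
  ln-linear range, the first-order fit ln X = a − k·t, t½ = ln 2 / k, and
  intrinsic clearance scaled with the well-stirred-model factors,

      CL_int = (0.693 / t½) · (mL incubation / mg microsomes)
                            · (mg microsomal protein / g liver)
                            · (g liver / kg body weight),

  followed by low/intermediate/high clearance banding (defaults 8.6 and
  47 µL/min/mg).
* **Composite site lability** — CSL = k_total/(k_total + k_w) aggregation of
  user-supplied per-site lability rate constants, with a per-site
  contribution table.
* **Synthetic data** — seeded simulators for calibration sets, QC tables,
  matrix-effect sample pairs, depletion time courses (exponential decay
  toward a plateau), and Gaussian-peak MRM chromatograms with trapezoidal
  peak integration, all returning their ground truth.

## Worked example

A human-liver-microsome incubation sampled at 0–70 min, entered as per-time
mean concentrations (ng/mL):

```r
library(metstabr)

tc <- time_course(time = c(0, 2.5, 7.5, 15, 20, 30, 40, 50, 60, 70),
                  measured_conc = c(584, 534, 457, 367, 308, 214,
                                    187, 165, 158, 154))
run_metstab(tc)
#> In vitro metabolic stability (substrate depletion)
#>   linear range : 0-30 min (r^2 = 0.998)
#>   k            : 0.0329 1/min
#>   t1/2         : 21.05 min
#>   CL_int       : 32.93 uL/min/mg  |  38.53 mL/min/kg
#>   class        : intermediate
```

The curve decays first order up to 30 min and then flattens (cofactor
depletion / enzyme inactivation), so the range selector keeps the 0–30 min
prefix (six points, r² = 0.998; adding the 40 min point drops r² below the
0.99 threshold). The slope of ln X over that range is the depletion rate
constant k; ln 2/k gives the in vitro half-life; the scaling factors
(1 mL/mg, 45 mg protein/g liver, 26 g liver/kg) convert it to intrinsic
clearance, which lands in the intermediate band.

A calibration fit on simulated standards with known ground truth:

```r
cal <- simulate_calibration(sim_config(seed = 42))
m <- fit_calibration(cal$standards, weighting = "1/x")
m
#> Calibration model: y = 1.6988x + 3.79183  (weighting 1/x, n = 8)
#>   r^2 = 0.9998, SD(intercept) = 0.656341
round(lod_loq(m), 3)
#>   lod   loq
#> 1.275 3.864
```

The fitted slope/intercept sit near the generator's truth (1.7298,
3.62941); the LOD/LOQ pair always has ratio 10/3.3.

The same pipeline is scriptable via the bundled CLI
(`inst/cli/metstab`): `metstab metstab --timecourse timecourse.csv
--range 0:30 --report out.json`, with subcommands `simulate`, `calibrate`,
`validate`, `metstab`, `csl`, and `all`, each writing one JSON report with a
configuration echo.

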