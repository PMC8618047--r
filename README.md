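# thermoparam

Physiological heat-source parameters from infrared breast thermograms.

An abnormally active region inside the breast acts as a localized heat
source under the skin. In the steady state, the analytical point-source
solution of the bio-heat balance predicts the skin surface temperature
at radial distance *a* from the surface projection of a source of
intensity *q* (W) buried at depth *d* (m):

    T(a) = Te + q / (4 π h0 (d² + a²))

with ambient temperature `Te` and skin-to-air heat-exchange coefficient
`h0` (8.77 W/m²·°C by default). A spherical source of radius *R* obeys
the same law with effective depth *d + R*.

`thermoparam` inverts the mean radial surface-temperature profile
around the hottest spot of a thermogram to these parameters by two
methods —

* **D-I-R closed form**: `d = a·√((T(a)−Te)/(Tmax−T(a)))`,
  `q = 4π h0 a² (T(a)−Te)(Tmax−Te)/(Tmax−T(a))`, evaluated at a single
  extraction radius *a*;
* **Lorentz fit**: whole-profile least squares of
  `y = A/(a² + w²) + y0`, giving `d = |w|` and `q = A` under the
  `4π h0 ≡ 1` convention —

and assembles the five-feature pattern vector `{Tmax, d, q, R, θ}`
(radius feature `R = (q/(Qm·At))^⅓`, inclination
`θ = arctan(q/a)` in degrees). A radial-basis SVM under stratified
10-fold cross-validation classifies normal versus abnormal
thermograms, and a scan over the extraction radius (0.0006–0.018 m in
pixel-size steps) finds the position with the highest correct
classification rate (CRC). A seeded synthetic thermogram/cohort
generator with known ground truth serves as the validation bed.

It is intended for researchers working on physiology-based analysis of
thermal images who want a reproducible, scriptable reference pipeline
rather than an interactive tool.

## Worked example

```r
library(thermoparam)

# plant a source 1 cm deep whose hotspot sits 12 degC above ambient
q <- 4 * pi * 8.77 * 0.01^2 * 12
th <- synth_thermogram(c(120, 120), d = 0.01, q = q, shape = c(241, 241),
                       background = 22, noise_sd = 0, seed = 1)
profile <- extract_std_profile(th)
heat_source_fit(profile, method = "dir", a = 0.0168)
#> Heat-source fit (D-I-R closed form) at a = 0.0168 m
#>    Tmax       d       q       R   theta
#> 34.0000  0.0100  0.1322  0.0681 82.7603
#> Profile R-squared: 1.0000
```

The inversion recovers the planted depth (0.0100 m) and intensity
(0.1322 W) exactly; `Tmax` is the hotspot temperature in °C, `R` the
monotone radius feature derived from `q`, and `theta` the inclination
angle of the intensity–position ratio in degrees.

Cohort-level classification with the position scan:

```r
coh <- synth_cohort(cohort_spec(n_normal = 12, n_abnormal = 10,
                                shape = c(200L, 240L), margin = 40L,
                                seed = 42))
profiles <- lapply(coh$thermograms, extract_std_profile)
scan_positions(profiles, "dir", K = 5, seed = 7)
#> RoI position scan (D-I-R, 30 positions, 5-fold CV)
#>   optimal a = 0.0006 m: CRC 100.00%, AUC 1.0000
#>   accuracy 100.00%, sensitivity 100.00%, specificity 100.00%
```

The synthetic classes have disjoint depth/intensity ranges, so an
out-of-fold CRC of 100 % and AUC of 1 at some radius is the expected
behaviour; `report(scan, "results/")` writes the per-position CRC,
metrics and ROC tables as CSV.

A command-line wrapper over the same functions is installed at
`exec/thermoparam` (subcommands `simulate`, `roi`, `extract`,
`classify`).

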