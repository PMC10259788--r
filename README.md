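# circout

Robust outlier detection for **linear-circular nonparametric regression**:
an angular response (wind direction, headings, phases) regressed on a real
predictor, with heavy-tailed wrapped Cauchy errors.

Classical "distance from the mean" diagnostics fail on the circle: the
residual of an angle is an arc length bounded by π, and the circular mean
direction is not robust once outliers skew the residual distribution. The
detector implemented here works in the residual domain with the **circular
median**:

1. Fit the regression by Nadaraya–Watson (NW) or local-linear (LL)
   circular-response kernel smoothing (Gaussian kernel, leave-one-out
   cross-validated bandwidth). The fitted angle is
   `atan2(Σ wᵢ sin θᵢ, Σ wᵢ cos θᵢ)` (NW), or the `atan2` of local-linear
   smooths of the sine and cosine components (LL).
2. Compute absolute circular residuals `eᵢ = π − |π − |θᵢ − m̂₋ᵢ(xᵢ)||`
   from the leave-one-out fitted values (deleted residuals, so an outlier
   cannot mask itself through its own fitted value).
3. Compute each residual's circular distance `distᵢ` from the residuals'
   circular median.
4. Flag observation *i* as an outlier when `distᵢ` exceeds a cut-off
   calibrated by Monte Carlo under the clean model — the mean *q*-quantile
   (q = 0.90/0.95/0.99) of the `distᵢ` across simulated replicates, as a
   function of sample size *n*, error concentration ρ, and estimator.

The package ships the full reference cut-off grid, regenerates any cell
(`generate_cutoffs`), interpolates between cells (`lookup_cutoff`),
offers a data-adaptive parametric-bootstrap cut-off for real datasets
(`bootstrap_cutoff`), tests the wrapped Cauchy error assumption with a
bootstrap-calibrated Watson U² (`wcauchy_gof_test`), and includes the
simulation-study machinery (contamination by `γπ` shifts; masking,
swamping and true-detection rates; `run_design`).

## Worked example

```r
library(circout)

# synthetic benchmark: n = 100, concentrated WC(0, 0.90) errors,
# five responses shifted by 0.85*pi
d <- make_fixture("model", n = 100, rho = 0.90, gamma = 0.85,
                  fraction = 0.05, seed = 7)
attr(d, "outliers")
#> [1] 12 52 55 79 96

detect_outliers(d, method = "LL", q = 0.95, cutoff_source = "table")
#> Circular-median outlier detection (LL, q = 0.95)
#>   n = 100, bandwidth h = 0.4307, residual rho_hat = 0.8527
#>   cut-off (table) = 1.2840 rad
#>   flagged observations: 12, 14, 52, 79, 96
```

The detector recovers four of the five planted outliers (12, 52, 79, 96),
misses one (55) and wrongly flags one inlier (14): with five shifted
points in a sample of 100 this is TDR = 0.8, masking = 0.2, swamping ≈
0.01, the regime the calibration predicts for ρ = 0.90. The reported
`rho_hat` is the wrapped Cauchy concentration fitted to the signed
residuals and is what enters the cut-off table lookup.

Checking the error assumption on an applied dataset:

```r
w <- make_fixture("scada_like", seed = 7)   # synthetic wind-speed/direction pairs
wcauchy_gof_test(w$y, reps = 500, seed = 3)
#> Watson U-squared test of the wrapped Cauchy hypothesis
#>   fitted mu = 1.8674, rho = 0.0662 (moment), n = 55
#>   U^2 = 0.03329, bootstrap p-value = 0.4340 (500 reps)
#>   level 0.9: critical value 0.05306 -> retain
#>   ...
```

A command-line front end (`inst/cli/circout`) wraps detection, cut-off
generation, the simulation runner, the goodness-of-fit test and fixture
generation for shell use, e.g.

```sh
Rscript inst/cli/circout detect --input data.csv --x-col wind_speed \
    --y-col wind_dir --units degrees --method LL --q 0.95 --report out.json
```

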