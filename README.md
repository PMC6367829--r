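# interplay4d

Simulation framework for the **interplay effect** in pencil-beam-scanning
(PBS) proton therapy of abdominal (pancreatic) targets under periodic
breathing motion, and for its mitigation by fractionation.

PBS delivers dose spot by spot over tens of seconds. When the target moves
with breathing (period *T* ∈ [2.8, 10] s, dominant inferior–superior
amplitudes up to 15 mm), the delivery clock interferes with the motion and
single fractions develop hot/cold spots inside the clinical target volume
(CTV) even though the time-averaged geometry is covered. The package
quantifies this with:

* a **synthetic patient**: HU phantom with GTV/CTV/ITV/PTV and OARs (liver,
  kidneys, spinal cord, bowel), plus 20-phase periodic deformation vector
  fields `u_j(x) = sin²(πj/20) · U(x)` with patient-like amplitudes and
  day-to-day variation across repeated "measurements";
* **deformation QA**: Jacobian-determinant maps det(I + ∇u) and the
  mass-conservation ratio m_EEX/m_EIN from a generic HU-density table;
* a **simplified PBS engine**: power-law range–energy
  (R[cm] = 0.0022·E^1.77), analytic Bragg depth dose, lateral Gaussian
  σ(wepl) = 3 mm + 0.025·wepl, BEV WEPL ray tracing, SFUD two-field plans
  (non-negative least-squares spot weights) and a delivery timeline
  (5 ms dwell, 3 ms moves, 1 s energy-layer switches);
* **4D dose accumulation**: spots are binned to breathing phases via
  `phase(t) = (start + ⌊20t/T⌋) mod 20`, deposited on the warped phase CT
  with re-traced WEPL, and pulled back to the reference frame;
* **fractionation Monte Carlo**: per-fraction random motion input and
  per-field starting phases (i, k), cumulative metrics for n = 1…28
  fractions, and the single- vs multi-measurement longitudinal experiment;
* **metrics and statistics**: DVH metrics (dmean, d2, d5/d95, v95, v107,
  v30), one-sided Wilcoxon rank-sum comparisons, and weighted Pearson
  correlations with the significance statistic
  t = ρ·√((N−2)/(1−ρ²)) against the one-sided 95% Student-t critical
  value.

Everything is tidyverse-shaped: metric tables are tibbles, results have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(interplay4d)

# phantom with a 51.9 cc CTV and an 8 mm IS / 3 mm AP / 2 mm LR breathing
# pattern at T = 3 s, plus period-rescaled repeats at 5.5 s and 10 s
ph <- build_phantom(phantom_config(64, 3.75, ctv_volume_cc = 51.9))
m1 <- generate_motion_input(ph$ct, ph$structures$CTV, c(2, 3, 8), 3.0, id = "m1")
scen <- patient_scenario(ph$ct, ph$structures,
                         list(m1, rescale_period(m1, 5.5, id = "m2"),
                              rescale_period(m1, 10, id = "m3")))

plan <- plan_sfud(scen)                       # two-field SFUD plan
static <- compute_static_dose(plan, scen$ct)  # 3D dose (3DDC)
dose_report(static, scen$structures, which = "CTV")
#> # A tibble: 1 × 9
#>   structure dmean    d2    d5   d95 d5d95   v95  v107   v30
#>   <chr>     <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 CTV       100.0  102.  101.  98.7  1.03   100     0   100

tab <- interplay_table(plan, scen)            # precomputed 4D point doses
ens <- enumerate_single_fraction(tab)         # 4Dx1: 20 x 20 starting phases
summary(ens$d5d95)                            # single-fraction interplay
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.135   1.176   1.192   1.194   1.209   1.279

sims <- lapply(1:24, function(r) simulate_treatment(tab, 28, seed = r))
fc <- fractionation_curve(sims)               # 4Dx28 mitigation
dplyr::filter(fc$curve, metric == "d5d95", n %in% c(1, 7, 28))
#> # A tibble: 3 × 5
#>       n metric median    q5   q95
#>   <int> <chr>   <dbl> <dbl> <dbl>
#> 1     1 d5d95    1.18  1.15  1.23
#> 2     7 d5d95    1.07  1.05  1.10
#> 3    28 d5d95    1.04  1.04  1.06
```

Single fractions show pronounced interplay (median d5/d95 ≈ 1.19, CTV
coverage v95 dropping well below 100%); accumulating 28 fractions with
random starting phases and motion patterns returns the homogeneity to
within ~0.02 of the static plan (d5/d95 ≈ 1.03) — the fractionation
mitigation the package is built to study. `run_study()` chains the whole
pipeline (phantom → QA → plan → 4Dx1 → 4Dx28 → correlations) for a
multi-patient configuration, and `correlation_suite()` reports the four
cohort correlations with their t-statistics.

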