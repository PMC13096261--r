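# segdosim

Segmentation is one of the largest operator-dependent steps in the
dosimetry workflow for Lu-177 radiopharmaceutical therapies (DOTATATE,
PSMA): two centres given the same quantitative SPECT/CT series can report
substantially different organ and lesion absorbed doses purely because they
drew different volumes of interest (VOIs). `segdosim` is an R package for
physicists and dosimetry researchers who want to quantify, on controlled
synthetic ground truth, how specific segmentation choices — including or
excluding the renal pelvis and cysts, the percentage-of-maximum threshold
applied to a lesion, propagating a VOI across time points versus
re-segmenting, taking mass from CT versus from the SPECT VOI — propagate
into absorbed-dose variability.

The package provides four layers:

1. **Digital phantom** — a deterministic, seeded abdominal phantom
   (kidneys with renal pelvis and cysts, liver with hot lesions, spleen)
   with per-region kinetics, an isotropic Gaussian PSF and optional
   Poisson-like noise, sampled at four post-injection time points
   (3.7, 27.7, 103.1, 124.0 h by default).
2. **Segmentation emulators** — `threshold_voi()` (percentage-of-maximum,
   restricted to the 26-connected component containing the hottest voxel),
   `propagate_voi()` (integer-voxel translation, no reshaping),
   `sphere_voi()`, `combine_voi()` and `estimate_mass()` (constant CT mass
   vs variable SPECT mass at 1.0 g/mL).
3. **Dosimetry chain** — activity recovery with no partial-volume
   correction, mono-exponential time–activity fitting by
   Levenberg–Marquardt (`fit_tac()`), analytic time-integrated activity
   coefficients (`tiac()`), and a local electron-deposition absorbed dose
   (`absorbed_dose()`).
4. **Dispersion statistics** — quartile coefficient of dispersion,
   subset-weighted QCD, paired percent dose differences and weighted IQR
   (`qcd()`, `qcd_weighted()`, `delta_ad()`, `summarize_cohort()`), plus
   orchestrated experiments (`run_voi_scenarios()`,
   `run_threshold_sweep()`, `simulate_cohort()`).

## The model

The time–activity curve of a VOI is fitted as

    A(t) = A0 · exp(−λ_eff · t)

by nonlinear least squares (Levenberg–Marquardt, log-linear
initialisation, λ_eff > 0 enforced). The time-integrated activity
coefficient is the analytic 0→∞ integral normalised by the injected
activity,

    TIAC = (A0 / λ_eff) / A_inj        [hours]

and the absorbed dose under complete local electron deposition is

    D = TIAC · A_inj · Δ / m           [Gy]

with Δ = 8.53·10⁻² Gy·g·MBq⁻¹·h⁻¹, the mean electron energy emitted per
Lu-177 decay (147.9 keV), and m the VOI mass at 1.0 g/mL. Photon
cross-dose is deliberately not modelled; for Lu-177 organ self-dose the
electron term dominates.

Cohort variability is summarised with quartile-based statistics, robust to
the skewed, outlier-prone dose distributions of multi-centre comparisons:

    QCD  = (Q3 − Q1) / (Q3 + Q1)
    QCDw = (n_RTStruct · QCD_RTStruct + n_mask · QCD_mask) / n_total
    ΔAD/AD̄_task4 = 100 · (AD_task1 − AD_task4) / mean(AD_task4)

where task 1 is participant-drawn segmentation and task 4 the provided
reference VOIs; the difference `QCD(task 1) − QCDw(task 4)` isolates
segmentation-induced variability.

## Worked example

```r
library(segdosim)

spec    <- default_phantom_spec(seed = 1)
anatomy <- build_anatomy(spec)
series  <- make_activity_series(anatomy, spec)

report <- run_voi_scenarios(series, anatomy, injected_activity_MBq = 7210)
report[report$kidney == "R", c("scenario", "volume_ml", "tiac_h", "dose_Gy",
                               "pct_diff_volume", "pct_diff_tiac",
                               "pct_diff_dose")]
#>           scenario volume_ml tiac_h dose_Gy pct_diff_volume pct_diff_tiac
#>  refined_reference       152  0.514    2.08            0.00         0.000
#>        plus_pelvis       172  0.539    1.93           12.82         4.903
#>         plus_cysts       158  0.518    2.01            4.04         0.816
#>  pct_diff_dose
#>           0.00
#>          -7.02
#>          -3.09
```

Reading the right-kidney rows: adding the renal pelvis to the functional
parenchyma VOI inflates its volume (and hence mass) by 12.8% but its TIAC
by only 4.9% — the pelvis is hot only transiently, from early urinary
excretion — so the absorbed dose *drops* by 7.0%. Adding the cold cysts
inflates mass by 4.0% against a 0.8% TIAC gain (blur spill-in only), a
3.1% dose underestimate. Mass always inflates faster than TIAC when the
added structure is cold at late time points; that asymmetry is the
mechanism by which inconsistent pelvis/cyst handling spreads reported
kidney doses.

The same phantom supports lesion threshold sweeps
(`run_threshold_sweep()`: dose falls with threshold under a constant CT
mass, rises under a SPECT-derived mass) and synthetic submission cohorts
(`simulate_cohort()` + `summarize_cohort()`), e.g.

```r
lesion <- true_voi(anatomy, "lesion_1")
liver  <- combine_voi(true_voi(anatomy, "liver"), lesion, "difference")
compute_tbr(series, lesion, liver, 7210, 70)
#> [1] 12.7
```

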