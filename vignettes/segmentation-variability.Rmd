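---
title: "Methods: segmentation-driven variability in Lu-177 dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-driven variability in Lu-177 dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdosim)
```

## Scope and rationale

`segdosim` studies a single question: holding the dosimetry workflow
fixed, how much do absorbed-dose estimates move when only the
segmentation changes? Real multi-centre submission data cannot answer
this cleanly — participants differ in fitting, integration and dose
conversion too — so the package works on synthetic ground truth where
the "true" VOI of every structure is known by construction, and every
segmentation variant runs through one identical dose chain.

## The digital phantom

`default_phantom_spec()` defines a 96³ volume at 4 mm isotropic spacing
(384 mm field of view), populated with sphere/ellipsoid organs: liver
with two hot lesions, spleen, and two kidneys each composed of
functional parenchyma, a renal pelvis and a cyst (intraparenchymal on
the left, extraparenchymal on the right). Voxel membership is decided
by whether the voxel centre lies inside the analytic primitive, which
makes rasterisation checkable against a brute-force voxel scan.
Structures are rasterised in declaration order and later structures
overwrite earlier ones, so the pelvis and cysts carve the parenchyma
and all labels are disjoint — exactly the property the kidney VOI
scenarios need (parenchyma alone, parenchyma ∪ pelvis, parenchyma ∪
cysts, built by set union of labels).

Each region follows mono-exponential kinetics `C0·exp(−λ_eff·t)` (an
uptake–washout form `C0·(1−e^{−μt})·e^{−λt}` is available per region).
The defaults are chosen so the chain lands in the range seen in
post-therapy Lu-177 DOTATATE imaging with a ~7.2 GBq administration:

| region | C0 (MBq/mL) | λ_eff (1/h) | rationale |
|---|---|---|---|
| kidney parenchyma | 0.42–0.45 | 0.014 | ~50 h effective half-life; kidney TIAC ≈ 0.5 h, dose ≈ 2 Gy |
| renal pelvis | 1.0 | 0.150 | transiently hot from urinary excretion, essentially gone by the second scan |
| cysts | 0 | — | no radiopharmaceutical uptake; any apparent signal is PSF spill-in |
| lesions | 2.2–3.0 | 0.009–0.010 | SUVmax ≈ 20 and a tumour-to-background ratio near 13 at the second time point, inside the clinically reported span |
| liver / spleen / background | 0.25 / 0.35 / 0.03 | 0.012–0.020 | typical organ uptake hierarchy |

Acquisition times default to 3.7, 27.7, 103.1 and 124.0 h
post-injection with 7210 MBq injected — a published four-scan
post-therapy protocol.

**Imaging model.** Volumes are blurred with an isotropic Gaussian PSF
(default FWHM 12 mm, a SPECT-like value; patient-system PSFs are not
published for the reference protocol, so this is a declared default,
not an inference). The blur is a separable convolution with a kernel
truncated at 4σ and constant-zero padding; total activity of interior
structures is conserved to <0.5%. Optional noise (`noise_model =
"poisson_like"`) adds independent Gaussian deviations with variance
proportional to the local mean (standard deviation
`noise_scale·sqrt(mean)`), clipped at zero and fully governed by the
spec seed.

**The default is noise-free.** The phantom's purpose is to expose the
*segmentation* mechanism; reconstructed-SPECT noise is a different
variability source, out of scope, and the monotonicity statements the
package makes (below) are statements about the noiseless mechanism.
Consequences: passing tests show that the segmentation-to-dose
machinery behaves correctly and that the cold-structure and threshold
mechanisms operate as described; they do not show robustness to
reconstruction noise, motion, heterogeneous uptake within a region, or
non-ellipsoidal anatomy — real images have all four.

## Segmentation emulators

*Threshold* (`threshold_voi()`): voxels ≥ fraction × maximum. The
maximum is taken inside an optional search region (practitioners crop
before thresholding; whether original submissions used cropped or whole
images is unknowable, so both are supported). The superlevel set is
reduced to the 26-connected component containing the hottest voxel —
without this restriction a global threshold merges organs of similar
uptake; it is switchable (`connected = FALSE`). Sweeps use thresholds
10–75% in 5% steps.

*Propagation* (`propagate_voi()`): the "segment once, shift to the
other time points" behaviour. Positional adjustment is an integer-voxel
translation maximising enclosed activity within a ±5-voxel search
window around the activity-centroid displacement; sub-voxel shifts are
rejected deliberately, since interpolation would reshape the mask and
the defining property of propagation is an unchanged voxel count. Ties
prefer the smaller shift. Sweeps seed the threshold on the second scan
and propagate to later time points *and backwards to the first* — the
convention for the earlier scan is genuinely open, and the symmetric
choice keeps one VOI shape per lesion.

*Mass* (`estimate_mass()`): uniform density 1.0 g/mL. `ct_constant`
fixes mass from an anatomical reference VOI regardless of threshold;
`spect_variable` takes mass from the SPECT VOI itself (per time point,
or averaged over time points — the averaging convention is used for
kidney scenario reporting and lesion sweeps). A CT-density-weighted
mass is intentionally absent: the phantom carries no independent CT
intensities.

## Dosimetry chain

Activity in a VOI is the plain voxel sum times voxel volume — no
partial-volume correction, matching the convention that activity and
mass come from the same VOI. Fits use `minpack.lm::nlsLM`
(Levenberg–Marquardt), initialised from a log-linear regression on the
positive samples, with λ bounded positive. Four samples cannot support
a free bi-exponential, so the model is mono-exponential only.
Degenerate inputs are errors, not silent fixes: all-zero curves,
non-decaying data (log-linear slope ≥ 0), empty VOIs under a
mass-from-VOI strategy. An empty VOI during activity measurement yields
zero activity with a warning flag, so a sweep row can be flagged rather
than aborting the whole factorial.

TIAC is the analytic 0→∞ integral `(A0/λ)/A_inj` — no
trapezoid/analytic hybrid, so every scenario is integrated identically.
Absorbed dose uses the local electron-deposition factor Δ = 8.53e−2
Gy·g·MBq⁻¹·h⁻¹ (147.9 keV mean electron energy per Lu-177 decay). This
replaces S-value dosimetry: it is the dominant self-dose term for
Lu-177, it is desk-computable, and it keeps the dose linear in TIAC and
1/mass so segmentation effects are not confounded by organ-geometry
factors. The missing photon cross-dose means absolute doses
underestimate a full S-value calculation by several percent (the
package's sanity check bounds this at 15% for a published kidney case);
*percent differences between scenarios*, the package's primary output,
are unaffected by any multiplicative dose constant.

## The two controlled experiments

**Kidney VOI scenarios** (`run_voi_scenarios()`): the refined reference
(parenchyma only) versus pelvis-added and cysts-added VOIs, one
identical chain throughout. The mechanism the phantom reproduces: a
structure that is cold at late time points adds proportionally more
mass than TIAC, so dose falls — and the pelvis (large, transiently hot)
depresses dose more than the cysts (small, never hot).

**Lesion threshold sweep** (`run_threshold_sweep()`): full factorial of
14 thresholds × {independent, propagated} × {ct_constant,
spect_variable}. On a centrally peaked (blurred) lesion, constant-mass
dose is non-increasing in threshold (higher threshold discards
activity at fixed mass) while variable-mass dose is non-decreasing over
low-to-mid thresholds (the surviving core has higher mean
concentration). These are asserted as monotonicity properties, not
absolute values: absolute sweep doses are patient- and
geometry-specific and are not claimed to match any published case.

## The synthetic cohort

`simulate_cohort()` generates submission tables for the dispersion
statistics. Each synthetic participant draws a segmentation method from
the configured mix (defaults follow the observed frequencies in
multi-centre Lu-177 submissions: manual-dominant for organs at 53.5%,
threshold-dominant for lesions at 33.2%), then method-specific
parameters. Contour-style kidney participants independently include the
renal pelvis with probability 1 − 0.673 and cysts fully/partially with
probabilities 0.654/0.135 — the observed inclusion frequencies. Lesion
thresholds are drawn uniformly on 0.11–0.75 (the observed range);
manual/semi-automatic contours are the reference VOI randomly
eroded/kept/dilated by one voxel; spheres are placed at the region
centroid with radius 0.5 ± 0.15 of the equivalent radius. The
one-voxel morphology and the sphere-radius fractions are invented
emulator knobs — submission papers report outcomes, not generative
parameters — and are exposed in `cohort_sim_config()` precisely because
they are conventions, not measurements. Task-4 doses are deterministic
per VOI format: binary-mask users get the refined reference, RTStruct
users a one-voxel-dilated version (emulating the systematic
contour-rasterisation offset between formats). Within a format the
task-4 QCD is therefore exactly zero and the reported QCD difference
isolates task-1 segmentation spread — the quantity of interest.

The default cohort size is 33 participants per patient-phantom (the
per-patient size of the paired multi-centre analyses this machinery is
designed for). `summarize_cohort()` never trims outliers: all
variability metrics use the complete dataset, and "range" is max −
min, labelled as such.

## Numerical conventions

- Quartiles: linear interpolation (`stats::quantile` type 7), fixed
  package-wide. No convention is universal and QCD shifts across
  conventions on small n, so the choice is pinned and documented.
- QCD is stored as a fraction and multiplied by 100 only in reports.
- The mean task-4 dose in ΔAD pools both VOI formats (a per-format mean
  is an easy variant but the pooled mean matches the statistic's
  definition).
- Report CSVs are written at 15 significant digits with fixed column
  order, so same-seed runs are byte-identical.
- All randomness (noise, cohort draws) descends from a single integer
  seed; anatomy and the noise-free series are seed-independent.

## Problem sizes

The shipped defaults — 96³ phantom for the experiments and acceptance
script, a 48³ phantom for the unit-test fixtures, 500 replicates for
the noisy-fit recovery check, 20 paired replicates for the
threshold-dispersion comparison — were chosen as the smallest sizes at
which the geometric structures are comfortably resolved at 4 mm voxels
and the stochastic checks are stable across seeds.

## Known limitations

- Ellipsoid/sphere anatomy only; no cortical defects, no lobulated
  lesions, no organ motion between time points (propagation is
  therefore exercised mainly through constructed translations).
- No SPECT projection/reconstruction: the PSF-plus-noise surrogate
  cannot reproduce correlated reconstruction noise or partial-volume
  behaviour beyond Gaussian spill.
- No partial-volume correction anywhere, by design; comparisons are
  between uncorrected quantities.
- Electron-only dose factor: absolute doses exclude photon cross-dose.
- The cohort simulator reproduces method *frequencies* and plausible
  perturbation shapes, not any specific participant population; its
  dispersion statistics exercise the machinery and the mechanism, and
  are not estimates of published cohort values.
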