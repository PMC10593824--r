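---
title: "APT-weighted CEST quantification and reproducibility with CESTrepro"
author: "CESTrepro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APT-weighted CEST quantification and reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CESTrepro)
```

## The problem

Chemical exchange saturation transfer (CEST) MRI detects dilute solute
protons — for amide proton transfer (APT) imaging, the backbone amide
protons resonating at +3.5 ppm from water — through their exchange-mediated
attenuation of the bulk water signal under off-resonance saturation. The
measured quantity is the Z-spectrum, the normalized water signal
$z(\Delta\omega) = S_{sat}(\Delta\omega)/S_{ref}$ as a function of the
saturation offset. APT-weighted contrast is of clinical interest in brain
tumor imaging, where it tracks elevated mobile protein content; whether its
readouts are *reproducible* — across repeated scans, across days, across
scanners — decides whether they can serve as quantitative biomarkers.

CESTrepro implements the full quantification chain for 3T brain APT
imaging together with the statistical battery used to assess test–retest
reproducibility, driven by a synthetic multi-participant, multi-session,
multi-scanner phantom generator with known ground truth. Every downstream
claim the package makes is therefore checkable against the generating
parameters.

## The model

### Two-pool Lorentzian fit

Each voxel's Z-spectrum is modeled as a constant baseline minus two
Lorentzian lines,
$$\hat z(\Delta\omega) \;=\; c \;-\; L_{ds}(\Delta\omega) \;-\;
L_{mt}(\Delta\omega), \qquad
L(\Delta\omega) = A\,\frac{(w/2)^2}{(w/2)^2 + (\Delta\omega-\delta)^2},$$
where the narrow pool is direct water saturation (DS) and the broad pool is
semi-solid magnetization transfer (MT). The fit is bounded nonlinear least
squares (Levenberg–Marquardt via minpack.lm, analytic Jacobian) restricted
to a *fit region* that excludes the band carrying the APT, amine and NOE
peaks: by default offsets with $|\Delta\omega| \le 1.25$ ppm or
$|\Delta\omega| \ge 8$ ppm. The exclusion band, the initial values
(DS: $A=0.9,\ \delta=0,\ w=1.5$ ppm; MT: $A=0.1,\ \delta=-1,\ w=40$ ppm)
and the box bounds (baseline $c \in [0.8, 1.2]$; DS center $\pm 1$ ppm,
width $[0.3, 10]$ ppm; MT center $[-3, 1]$ ppm, width $[10, 100]$ ppm) are
all configuration-exposed through `twoPoolFitControl()` and
`defaultFitRegion()`. The disjoint width bounds keep the two pools from
swapping roles; with this parameterization the noiseless fit recovers
generating parameters to better than $10^{-4}$ relative error (see the
test suite's fit oracle).

One caveat the tests quantify: pools *outside* the fit region still have
Lorentzian tails *inside* it (about $2\times10^{-3}$ of z near $\pm1$ ppm
for a 5% APT pool of 1 ppm width). Individual fitted parameters can
therefore be biased by a few percent even on noiseless data; the fitted
baseline at +3.5 ppm — the quantity the metrics consume — is stable to
about $2\times10^{-3}$, and the resulting LD recovers an injected 5% APT
amplitude to within 0.1 percentage points.

### B0 correction

Static-field inhomogeneity shifts the apparent water resonance. The
per-voxel shift is read off as the position of the minimum of the *fitted*
two-pool curve, located on a dense grid (0.01 ppm step over $[-2, 2]$ ppm;
ties break toward the smallest $|shift|$); voxels with $|shift| > 1$ ppm or
a non-converged fit are marked invalid. The measured spectrum is then
resampled at (nominal offsets + shift) by natural cubic-spline
interpolation, bringing the water minimum to 0 ppm. Offsets shifted beyond
the sampled range become missing for that voxel. We use the natural spline
rather than a shape-preserving (PCHIP) interpolant deliberately: with the
0.5 ppm sampling around the amide band, PCHIP systematically
under-resolves the shifted APT dip (errors up to $8\times10^{-3}$ in z),
while the spline keeps the corrected LD within 5% relative of its
unshifted value at a 0.4 ppm field offset.

Because the corrected spectrum lives in the shifted frame, the fitted
curve is evaluated at (target + shift) wherever the two are compared —
equivalent to shifting both, and exact on noiseless data. Applying the
correction twice is not an identity and triggers a warning.

### Metrics at +3.5 ppm

With $z$ the corrected spectrum and $\hat z$ the fitted two-pool baseline
(both evaluated at the APT offset, +3.5 ppm), all in percent:

* **LD** $= (\hat z - z) \times 100$ — the Lorentzian difference, positive
  where a saturation dip exceeds the DS+MT baseline;
* **MTRasym** $= (z(-3.5) - z(+3.5)) \times 100$ — the classic asymmetry,
  which conflates APT (positive) with NOE (negative) and also picks up the
  asymmetry of an off-center MT line (about $-0.7$% for a typical
  white-matter MT pool centered at $-1$ ppm);
* **MTRrex** $= (1/z - 1/\hat z) \times 100$ — the inverse-difference
  (spillover-resistant) form. It satisfies the exact pointwise identity
  $\mathrm{MTRrex}\cdot z\cdot\hat z = \mathrm{LD}$ (fractional units),
  which the tests assert to $10^{-10}$.

No $R_1$ scaling is applied to MTRrex: the protocol this package mirrors
acquires no T1 map, so relaxation compensation beyond the inverse
difference is not possible from the data at hand. A z floor of 0.05
guards the inversion near the water line; voxels below it are invalid.
These conventions reproduce the reported scale of brain tumor values
(contrast-enhancing tumor LD around 6–7%, MTRrex around 19–20%, healthy
white matter MTRasym around $-1$%) with the default synthetic tissues.

## The synthetic phantom

`generateDataset()` simulates one raw 4D volume per scan of a
reproducibility design (participants × scanners × sessions × repeats,
either fully crossed or the minimal plan holding exactly the scans the
three reproducibility levels need). The forward model is the same
Lorentzian superposition the analysis fits — deliberately, so that
recovery tests are exact in the noiseless limit; it is *not* a
Bloch–McConnell simulation, and saturation-train parameters are carried
as metadata only. Per voxel,
$$z(\Delta\omega) = b - \sum_{p} L(\Delta\omega - b_0(v);\, A_p, \delta_p, w_p),$$
scaled by a tissue reference intensity, with the local field offset
$b_0$ entering as a shift of the apparent pool centers. Reference frames
are simulated physically at the $-300$ ppm placeholder offset (four per
scan, the last used for normalization, configurable). Noise is additive
zero-mean Gaussian with sd = `noiseSd` × reference intensity on every
frame, clipped at zero as in magnitude images; at the SNR of interest the
Gaussian/Rician distinction is negligible and Gaussian noise keeps the
null distributions of the statistics simple.

The default tissue set (WM, GM, CSF shells; contrast-enhancing tumor rim
with necrotic core insert; background) uses invented four-pool
parameterizations chosen once so the emergent metric scales match
published 3T brain values; they are synthetic stand-ins, not measured
tissue parameters. The layout is deterministic concentric rectangular
blocks, so masks are exact by construction.

Reproducibility structure enters as *multiplicative lognormal
perturbations* of pool amplitudes: one factor per participant, per
participant×scanner, per participant×scanner×session, and per scan, with
ln-sd equal to the configured CV at that level (keeping amplitudes
positive). This is a phenomenological stand-in — the real drivers of
between-day variation (physiology, positioning, shim state) are not
modeled mechanistically — but it produces exactly the variance structure
the statistical battery is supposed to detect, which is what makes the
battery testable. Defaults: within-session 0.5%, between-session 1%,
between-scanner 2%, between-participant 10%, noise sd 0.005.

What the phantom does **not** emulate: k-space/readout effects, motion,
coils, registration error, partial-volume mixing at tissue boundaries,
B1 inhomogeneity, and Rician noise floors. Passing tests therefore
demonstrate correctness of the estimation chain under the stated model,
not robustness to every artifact of real acquisitions.

## The reproducibility battery

Per scan, ROI and metric, `buildReproTable()` records the mean over valid
masked voxels (empty ROIs are excluded with a logged reason, never
imputed). On that table:

* **COV**: per participant, $100\cdot sd/|\bar x|$ with the sample (n−1)
  standard deviation over the level's scans — within-session (the two
  repeats of session 1, scanner A), between-session (repeat 1 of sessions
  1–2, scanner A), between-scanner (repeat 1 of session 1, scanners A–B),
  and all-sessions; then the group median and Q1–Q3 across participants
  (linear-interpolation quantiles). For two scans the per-participant COV
  is $|x_1-x_2|/(\sqrt2\,|\bar x|)$, i.e. a half-normal variable with
  median $0.6745\,\mathrm{CV}$ under a true CV — the closed form the
  estimator tests check at n = 500.
* **Bland–Altman**: bias, sd of paired differences, limits of agreement
  bias ± 1.96 sd.
* **Mixed-effects test**: value ~ condition + (1 | participant), maximum
  likelihood, with a likelihood-ratio test of the condition term.
  Measured at the battery's design size (20 participants, 2 conditions,
  1000 null replicates) the LRT's type-I error is about 5.7% — inside the
  5 ± 2 band we require — so no small-sample correction is applied. A
  singular fit falls back to a fixed-effects block model, flagged.

### Sizing the variance-propagation experiment

The per-participant two-scan COV is $\mathrm{cv}_{\mathrm{eff}}\,|Z|$ with
$Z$ standard normal, so group *medians* of it are noisy. An a-priori
half-normal power calculation (independent of the pipeline) shows that
with level CVs of 0.5/1/2% the probability that the three group medians
order correctly in a single simulated study reaches ≥ 99.5% only around
48 participants with acquisition noise small relative to the level CVs.
The ordering experiment in the test suite therefore uses 48 participants,
`noiseSd = 0.001`, a 10×10×1 grid and the minimal scan plan — sizes
chosen from that calculation, not from the study defaults, which remain
6 participants and `noiseSd = 0.005`.

### Problem sizes

The test suite runs the fit oracle at 100 draws, the APT recovery at
~200 WM voxels over 20 noise seeds, the mixed-model calibration at 1000
null replicates, the COV ordering at 20 study seeds, and one full crossed
study on a 32×32×4 grid (6 participants, 8 scans each) twice to verify
bit-identical reproduction. `scripts/acceptance.R` re-derives the same
quantities at comparable sizes from a single command-line seed.

## Worked example

```{r example, eval = FALSE}
cfg <- phantomConfig(gridShape = c(16L, 16L, 2L), participants = 6L,
                     scanners = 2L, sessions = 2L, repeats = 2L,
                     seed = 1L)
report <- runStudy(cfg)
report
subset(report$covSummaries, roi == "WM" & metric == "LD")
report$blandAltman[["within_session.WM.LD"]]
subset(report$mixedModels, roi == "WM" & metric == "LD")
```

## Numerical choices and edge cases

* Offsets are canonicalized to 0.01 ppm resolution, so locating ±3.5 ppm
  is exact integer matching, never float comparison.
* Reference voxels below $10^{-6}\times$ the volume median intensity are
  invalidated (background air), not raised as errors.
* Fewer than 8 usable offsets in the fit region invalidates a voxel; NAs
  are dropped per voxel and counted in `nPointsUsed`.
* Validity is inherited strictly: metric voxels are valid only where the
  reference, the fit, and the B0 estimate all are, and (for MTRrex) both
  z and the fitted curve exceed the 0.05 floor.
* All randomness flows from the single integer seed in `phantomConfig()`;
  identical configurations give bit-identical datasets and reports.

## Known limitations

* The forward model matches the analysis model; the package cannot, by
  design, measure model error of the two-pool approximation itself.
* MTRasym inherits the asymmetry of an off-center MT line; the package
  reports it as measured rather than attempting MT-asymmetry correction.
* The mixed-effects LRT is slightly anticonservative at very small
  cohorts (it is calibrated at n = 20; at n = 6 expect inflated type-I
  error).
* No ICC or repeatability-coefficient variants, no multiplicity
  correction across ROIs/metrics — the battery mirrors the COV /
  Bland–Altman / mixed-model triad it set out to implement.
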