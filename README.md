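# CESTrepro

Quantification and test–retest reproducibility analysis of APT-weighted
CEST MRI, in R.

## What this is for

Amide proton transfer (APT) imaging is a chemical exchange saturation
transfer (CEST) MRI technique: off-resonance saturation of amide protons
(+3.5 ppm from water) attenuates the water signal in proportion to mobile
protein content, which is elevated in brain tumors. Before APT readouts
can serve as quantitative biomarkers, their repeatability (same session),
and reproducibility (across days, across scanners) must be established.

CESTrepro is aimed at CEST methods researchers and image analysts. It
implements, as tested S4-based building blocks:

* Z-spectrum normalization from raw saturation volumes (NIfTI I/O),
  z(Δω) = S_sat(Δω) / S_ref;
* voxelwise two-pool Lorentzian fitting of direct water saturation (DS)
  and semi-solid magnetization transfer (MT),
  ẑ(Δω) = c − L_ds(Δω) − L_mt(Δω), with
  L(Δω) = A (w/2)² / ((w/2)² + (Δω − δ)²),
  by bounded Levenberg–Marquardt with an analytic Jacobian;
* B0 inhomogeneity mapping from the shift of the fitted minimum, and
  voxelwise correction by cubic-spline resampling of the spectrum at
  (nominal offsets + shift);
* the three APT-weighted metrics at +3.5 ppm, in percent:
  LD = ẑ − z, MTRasym = z(−3.5) − z(+3.5), MTRrex = 1/z − 1/ẑ
  (satisfying MTRrex · z · ẑ = LD exactly);
* a synthetic multi-participant / multi-session / multi-scanner phantom
  generator with known ground truth (Lorentzian forward model, lognormal
  variance components per design level, simulated B0 fields, Gaussian
  noise);
* the reproducibility battery: per-participant within-subject COV
  (100 · sd/|mean|) summarized as group median [Q1–Q3] at the
  within-session / between-session / between-scanner / all-sessions
  levels, Bland–Altman limits of agreement, and linear mixed-effects
  testing (value ~ condition + (1 | participant), likelihood-ratio test).

The default offset schedule is the standard 43-offset scheme between
−100 and 100 ppm with dense sampling around water, plus four reference
images at −300 ppm (the last one used for normalization).

See `vignettes/cest-reproducibility.Rmd` for the model, its assumptions,
the design decisions, and known limitations.

## Worked example

Simulate a crossed 6-participant × 2-scanner × 2-session × 2-repeat study
on a 16×16×2 grid and run the full battery:

```r
library(CESTrepro)
cfg <- phantomConfig(gridShape = c(16L, 16L, 2L), participants = 6L,
                     scanners = 2L, sessions = 2L, repeats = 2L, seed = 1L)
report <- runStudy(cfg, rois = c("WM", "CE_tumor"), metrics = c("LD", "MTRrex"))
report
```

```
CEST reproducibility study report (seed 1)
  48 scans quantified, 480 ROI x metric x scan averages
  group median COV [Q1-Q3] (%):
    within_session   WM             LD        1.04 [0.97-1.27] (N=6)
    between_session  WM             LD        1.84 [1.15-2.08] (N=6)
    between_scanner  WM             LD        1.09 [0.17-2.11] (N=6)
    all_sessions     WM             LD        1.78 [1.32-2.18] (N=6)
    ...
    between_session  CE_tumor       MTRrex    2.50 [2.41-2.78] (N=6)
```

Each line is the group median (and interquartile range) of the
per-participant coefficient of variation of the ROI-averaged metric over
the scans that define that level — e.g. 1.04% scan-to-scan variation of
white-matter LD within one session. Agreement between two repeats and the
formal test for systematic differences:

```r
report$blandAltman[["within_session.WM.LD"]]
#> Bland-Altman (n = 6): bias 0.002, LoA [-0.165, 0.169]
subset(report$mixedModels, roi == "WM" & metric == "LD")
#>         condition roi metric     estimate         se    pValue significant
#> 1  within_session  WM     LD -0.002255213 0.03174610 0.9433786       FALSE
#> 2 between_session  WM     LD  0.013736183 0.04506550 0.7614062       FALSE
#> 3 between_scanner  WM     LD  0.046402448 0.05837373 0.4382771       FALSE
```

A near-zero Bland–Altman bias with tight limits of agreement and
non-significant condition effects is the expected picture for a phantom
whose only systematic structure is the injected level variance.

A thin command-line wrapper with `simulate`, `quantify` and `study`
subcommands lives at `inst/cli/cest-pipeline.R`; it reads a JSON config
mirroring `phantomConfig()` and writes NIfTI volumes, TSV tables and a
JSON report.

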