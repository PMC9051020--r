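---
title: "Models, parameters and design choices in hflpolar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in hflpolar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hflpolar)
```

# The measurement problem

The Henle fiber layer (HFL) — the radially running axons of the foveal
cone photoreceptors — is nearly transparent to conventional OCT, yet it
dominates the phase-retardation signal of the central macula in scanning
laser polarimetry (SLP). Two independent optical signatures therefore
exist for the same anatomy: its *thickness*, visible in directional OCT
when the imaging beam is offset in the pupil, and its *birefringence*,
visible in SLP intensity maps. This package implements the analysis chain
that correlates the two per subject and per cohort, plus a forward
simulator that generates both kinds of data with known ground truth.

# Polarization model

## Retarder composition

Every birefringent structure is modelled as a linear retarder with
retardance $\delta$ (radians; nm are converted at the 780 nm source
wavelength via $\delta = 2\pi\,\mathrm{nm}/780$) and slow axis $\theta$.
`composite_retardance()` composes two retarders as unitary Jones matrices
and reads the equivalent retardance off the eigenvalue phase difference;
`closed_form_retardance()` evaluates the same composition in closed form,

$$\cos(\delta/2) = \bigl|\cos\tfrac{\delta_1}{2}\cos\tfrac{\delta_2}{2}
 - \sin\tfrac{\delta_1}{2}\sin\tfrac{\delta_2}{2}\cos 2(\theta_1-\theta_2)\bigr|,$$

implemented through the rotation-vector (quaternion) components with
`atan2` rather than `acos`: near $|\cos(\delta/2)| = 1$ the `acos` form
loses half the floating-point digits (errors of order $10^{-8}$), while
the `atan2` form keeps the two routes within $10^{-9}$ everywhere, which
the test suite enforces on an 8,000-point grid.

A single-pass equivalent retarder represents each structure even though
the instrument is double-pass; the instrument literature specifies the
fixed compensator in single-pass terms (60 nm), so the whole model is
expressed on that scale.

## Why the macular cross is a second harmonic

With the HFL slow axis along the radial azimuth $\varphi$ and a residual
corneal retarder at fixed axis $\theta_c$, the composed retardance on a
ring depends on azimuth only through $\cos 2(\varphi-\theta_c)$. Fixed
(partial) compensation therefore yields ring profiles modulated at twice
the azimuthal frequency — the macular cross — and the fitted phase of
`cross_amplitude()` recovers $\theta_c$ modulo $\pi$. The $2\arccos(\cdot)$
nonlinearity adds a small fourth harmonic; at the default parameters it
carries < 1 % of the non-constant ring variance, which is exactly the
margin the acceptance suite checks. Variable compensation sets the
corneal residual to zero (an idealization of per-eye compensation), so
noiseless ring profiles are constant and the map is an annulus.

# Synthetic cohorts: the stated world

`sim_config()` freezes one "stated world"; its defaults and their origin:

| parameter | default | unit | origin |
|---|---|---|---|
| `t_max` | 45 | µm | healthy-adult histology/directional-OCT peak HFL thickness |
| `r_peak` | 2 | deg | thickness and retardation both peak near 2° in healthy eyes |
| `shape` | 2 | — | qualitative rise-then-fall; only stated qualitatively, chosen smooth |
| `coupling` | 0.45 | nm/µm | peak single-pass HFL retardance ≈ 20 nm at 45 µm |
| `corneal_residual_nm` | 60 | nm | magnitude of the fixed compensator element |
| `corneal_axis_deg` | 15 | deg | slow axis 15° nasally downward |
| `corneal_between_subject_sd` | 28 | nm | population corneal-retardance spread (25–35 nm in the GDx literature); also implied by fixed-mode CoV ≈ 31 % persisting at 2° |
| `noise_sd` | 2 | intensity | additive per-pixel detector noise |
| `baseline_sd` | 1 | intensity | between-session illumination/detector baseline |
| `thickness_cv` | 0.10 | — | between-subject spread of peak thickness |
| `gain` | 2 | intensity/nm | instrument calibration is unpublished; config parameter |
| `fov_deg`, `deg_per_px` | 20×40, 0.078 | deg | 20°×40° macular SLP raster at 256×512 px (true raster size unstated) |
| `oct_fov_deg`, `oct_n_cols` | 30, 1536 | — | high-resolution b-scan geometry |
| `axial_um_per_px` | 3.87 | µm/px | spectral-domain OCT axial pixel pitch |
| `trace_jitter_px` | 0.5 | px | manual-segmentation repeatability |

Between-subject draws (thickness scale, corneal residual magnitude,
baseline offset, fixation jitter, quality scores) derive deterministically
from one integer subject seed, so the SLP map and all four OCT scans of a
subject share the same anatomy, and identical seeds give byte-identical
output files.

Deliberate emulation choices:

- **Thickness model** is gamma-shaped — smooth, zero at the fovea, single
  peak — because only the qualitative shape (rise to 2°, then fall) is
  established.
- **Corneal residual in variable mode is exactly 0**; all of the
  fixed-vs-variable variability difference flows through
  `corneal_between_subject_sd`, the mechanism under test. The corneal
  *axis* is held fixed across subjects: ring means over full turns are
  axis-invariant, so axis spread would not change any statistic computed
  here.
- **Segmentation enters as boundary traces**, not rendered b-scans: the
  traces cover the central ±4.5° where the HFL is actually delineated,
  their jitter is a smooth spline perturbation (graders err smoothly, and
  never draw crossing boundaries), and directional visibility is encoded
  as validity masks (posterior border on the distal side of the 3 mm
  pupil offset, anterior on the proximal side).
- **Intensity is 8-bit quantized** with clipping to [0, 255], like the
  exported instrument maps.

What a green test does **not** establish: the simulator has no speckle,
no media opacity, no fixation drift within a scan, no macular pigment
dichroism or lens birefringence, no diseased or aged anatomy, and its
thickness–retardance coupling is exactly linear. Cohort R² values near
1.0 on simulated data are therefore an upper bound, not a prediction for
real cohorts, whose reported R² (≈ 0.8–0.9) includes all of the above.

# Analysis-stage conventions

- **Canonical grid**: 12 eccentricities, 0.25°–3.00° in 0.25° steps. The
  0° point is excluded: thickness and retardance both vanish there by
  construction and the correlation would be driven by a degenerate point.
- **320 µm/deg** converts eccentricity to retinal distance; no
  axial-length correction (none was available in the source protocol).
- **Quality control**: OCT kept iff quality > 20 dB (strict); SLP kept
  iff score ≥ 8 (inclusive). A failed scan drops the subject with a
  logged reason; nothing is imputed.
- **Fovea localization (OCT)** takes the argmax of the outer-segment
  band after an 11-column moving average (wide enough that single-column
  jitter cannot move the argmax); residual exact ties resolve toward the
  image center.
- **Macular center (SLP)**: fixed mode maximizes the mean second-harmonic
  variance fraction over rings at 1°–2° (coarse 0.25° grid then
  deterministic nested refinement to 0.1 px); variable mode starts from
  the centroid of the below-median region of the Gaussian-smoothed
  (σ = 0.25°) central 4°×4° patch and minimizes the variance of quadrant
  ring means. Both are seed-free; degenerate (structureless) maps raise
  errors rather than returning a center.
- **Ring statistics**: the headline per-ring statistic is the annulus
  mean (half-width 0.125°, so annuli tile without overlap) — "all points
  contained within" a ring; the thin-circle profile (360 bilinear samples)
  feeds the second-harmonic fit. Both are reported per subject so the
  cohort statistic can use either (`statistic: ring_mean` or
  `cross_amplitude`); the source protocol is ambiguous between them and
  the ambiguity is preserved explicitly.
- **Thickness combination**: thickness = posterior − anterior depth, each
  boundary taken from the offset scan on which it is valid; ≤ 10 % of
  columns may be interpolated/floored (with a warning counting floored
  columns), beyond that the input is rejected as a precondition violation.
- **Statistics**: Pearson R per subject (Fisher-Z averaging presupposes
  Pearson); subjects with |R| = 1 are excluded from the Fisher average
  with a warning (atanh diverges); quantiles use the linear-interpolation
  rule (R type 7); Mann–Whitney uses the exact permutation distribution
  when $n_a n_b \le 400$ with no ties, otherwise the normal approximation
  with tie and continuity corrections; α = 0.05 two-sided, no
  multiple-testing correction.
- **Medians "across all eccentricities"** pool subject × eccentricity
  values (not per-subject means); the alternative reading is noted but
  not used.

# Known limitations

- The intensity↔nm calibration and true SLP raster size are config
  parameters, not facts; absolute intensity levels are therefore
  arbitrary and only *relative* structure is meaningful.
- Meridian registration between OCT scan halves and SLP azimuth assumes
  axis-aligned instruments (temporal/nasal along the image row through
  the fovea).
- Left eyes are a metadata flag only; no mirroring is applied.
- Enhanced corneal compensation and diseased/aging cohorts are out of
  scope.

```{r example, eval = FALSE}
cfg <- sim_config()
sim <- simulate_retardation_map(cfg, "fixed", subject_seed = 42)
center <- locate_macular_center(sim$map)
slp_subject_profile(sim$map, center)
```
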