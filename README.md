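# hflpolar

Tools for quantifying the relationship between **Henle fiber layer (HFL)
thickness** and **macular phase retardation** in the human fovea, using the
two clinical imaging modalities that can each see the HFL by a different
physical mechanism:

- **Directional OCT**: displacing the OCT beam entry in the pupil exploits
  the HFL's angular scattering, delineating its posterior border on the
  distal side of the offset and its anterior border on the proximal side.
  Two opposite-offset b-scans per meridian are combined into a thickness
  profile.
- **Scanning laser polarimetry (SLP)**: the parallel microtubules of the
  foveal cone axons make the HFL birefringent with a radially oriented slow
  axis. Under *fixed* (partial) corneal compensation the HFL retarder beats
  against the residual corneal retarder and produces the classic *macular
  cross*; under *variable* (per-eye) compensation the map is an annulus.

Because the raw subject images behind published analyses of this kind are
generally not deposited, the package ships a **polarization-optics forward
simulator** that generates both kinds of input for cohorts of virtual
subjects with known ground truth, so every pipeline stage is verifiable by
parameter recovery.

## The model in brief

Each birefringent structure is a linear retarder. Two stacked retarders
(δ₁, θ₁) and (δ₂, θ₂) compose, via their 2×2 unitary Jones matrices, into
an equivalent retarder whose retardance δ satisfies

    cos(δ/2) = | cos(δ₁/2)cos(δ₂/2) − sin(δ₁/2)sin(δ₂/2)·cos 2(θ₁−θ₂) |

With the HFL slow axis along the radial azimuth φ and a fixed corneal
residual axis θ_c, the net retardance on a ring about the fovea is
modulated at exactly **twice** the azimuthal frequency — the macular cross.
The SLP stage therefore fits `a + b·cos 2φ + c·sin 2φ` to each circular
intensity profile (amplitude √(b²+c²)) and also averages all pixels in
0.25°-wide annuli (ring means), on the canonical grid of 12 eccentricities
0.25°–3.00°.

HFL thickness follows a gamma-shaped radial profile
`t(r) = t_max·(r/r_peak)^s·exp(s(1−r/r_peak))`: zero at the foveal center,
peaking at `r_peak = 2°`, as observed in healthy adults.

Per subject, thickness (four-meridian average, sampled every 0.25° using
320 µm/deg) and ring intensity are correlated (Pearson R across the grid);
cohort R is the Fisher-Z average `tanh(mean(atanh(Rᵢ)))` and the cohort
R² its square. Quality control keeps OCT scans with quality > 20 dB and
SLP images with score ≥ 8.

## Worked example

Simulate the two study-sized cohorts (11 subjects with fixed compensation,
25 with variable compensation) and run the full pipeline:

```r
library(hflpolar)
cfg <- list(cohort1_n = 11, cohort1_mode = "fixed",
            cohort2_n = 25, cohort2_mode = "variable",
            seed = 1, statistic = "ring_mean", log_level = "quiet")
res <- run_pipeline(cfg, "results_run")
print(res$cohort_summaries$cohort1)
print(res$cohort_summaries$cohort2)
```

```
<cohort_summary cohort1: n = 11>
  thickness median [q25, q75]: 9.32 [6.42, 10.57] px
  intensity median [q25, q75]: 98.00 [86.58, 183.58]
  Fisher-averaged R = 0.961 (R^2 = 0.924)
<cohort_summary cohort2: n = 24>
  thickness median [q25, q75]: 9.87 [6.69, 10.96] px
  intensity median [q25, q75]: 34.39 [22.06, 38.13]
  Fisher-averaged R = 1.000 (R^2 = 1.000)
```

What these numbers mean: HFL thickness (in OCT pixels, ~3.87 µm each)
peaks near 11 px at 2°; the fixed-compensation cohort shows much brighter
and much more variable intensities (the uncompensated corneal residual
differs across subjects) — one simulated subject of cohort 2 was removed
by the SLP quality filter, so n dropped from 25 to 24, just as real QC
removes subjects. Thickness and intensity profiles correlate almost
perfectly in this idealized world (R² 0.92 / 1.00); real cohorts are noisier.
The run also writes per-subject profile CSVs, per-cohort summary JSON and
CoV tables, Mann-Whitney cohort comparisons (`comparisons.json`) and a
Markdown report (`results_run/report.md`).

The same pipeline runs from the command line:

```sh
inst/cli/hflpolar simulate --n 25 --mode variable --seed 7 --out sim/
inst/cli/hflpolar run --config pipeline.cfg --out results_run/
```

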