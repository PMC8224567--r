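# gagcest

Simulation and quantification of **gagCEST MRI** of lumbar intervertebral
discs, with a cohort-level mixed-model analysis comparing adolescent
idiopathic scoliosis (AIS) patients to healthy controls.

Glycosaminoglycan (GAG) loss is the earliest, premorphologic step of disc
degeneration. gagCEST imaging detects it without contrast agents: saturating
the GAG hydroxyl protons near +1 ppm from water and scanning the saturation
offset ω yields a z-spectrum Z(ω) = S(ω)/S0, and the asymmetry

> MTRasym(Δω) = Z(−Δω) − Z(Δω)

averaged over the GAG-specific band Δω = 0.9–1.9 ppm (reported in %) is the
per-voxel *gag score*. Because the asymmetry is exquisitely sensitive to B0
inhomogeneity, every voxel's water center frequency is first estimated from
a WASSR acquisition with the **maximum-symmetry algorithm** — the shift δ
minimizing C(δ) = mean_i [Ẑ(2δ − ω_i) − Z(ω_i)]² — and the spectrum is
re-centered before the asymmetry is evaluated.

The package provides the full chain as tested, reusable functions:

| Stage | Functions |
| --- | --- |
| Lorentzian pool model + closed-form oracle | `pool_set()`, `analytic_mtrasym()`, `calibrate_gag_amplitude()` |
| Synthetic spine phantoms, B0 fields, acquisitions | `make_spine_phantom()`, `make_b0_field()`, `render_subject()` |
| Two-cohort study generator with known truth | `cohort_design()`, `simulate_cohort()` |
| z-spectrum core | `zspectrum()`, `zs_normalize()`, `zs_interpolate()`, `zs_shift()` |
| B0 mapping (WASSR maximum symmetry) | `mscf_offset()`, `compute_b0_map()` |
| Gag scoring | `mtrasym_curve()`, `gag_score()`, `mtrasym_map()` |
| Disc segmentation (Gaussian naive Bayes) | `train_nb()`, `segment_discs()`, `verify_rois()` |
| Scoliosis bookkeeping | `cobb_angle()`, `classify_affection()`, `affection_table()` |
| Cohort statistics (REML mixed model, marginal means at age 23.1) | `summarize_discs()`, `fit_lmm()`, `corrected_means()` |
| Orchestration + NIfTI/JSON/CSV/YAML I/O | `run_pipeline()`, `write_cohort()`, `read_stack()`, … |

The numbered scripts under `analysis/` drive the study end to end
(simulate → quantify → cohort model → affection analysis) and write their
tables under `results/`. The methods vignette
(`vignettes/gagcest-methods.Rmd`) documents the generative model, every
tunable parameter, the numerical choices and the known limitations.

## Worked example

```r
library(gagcest)

# a phantom whose NP/AF regions truly score 3.90 % / 2.37 %,
# corrupted by a smooth 0.3-ppm B0 field and 1 % noise
ph  <- make_spine_phantom(spine_geometry(188), seed = 8,
                          np_gag = 3.90, af_gag = 2.37)
b0  <- make_b0_field(dim(ph$labels), amplitude = 0.3,
                     pixel_mm = ph$pixel_mm, seed = 9)
acq <- render_subject(ph, b0, noise_sd = 0.01, seed = 10)

mask <- ph$labels > 9                            # disc voxels
b0m  <- compute_b0_map(acq$wassr, acq$s0, mask, acq$wassr_offsets)
gag  <- mtrasym_map(acq$cest, acq$s0, b0m, mask, acq$cest_offsets)
mean(gag[ph$labels %in% (10 + 1:5)], na.rm = TRUE)   # NP: 3.91
mean(gag[ph$labels %in% (20 + 1:5)], na.rm = TRUE)   # AF: 2.38
```

Running the whole simulated study (`analysis/01…04`) prints, for the
default seed-1 cohort (16 controls + 10 patients, 130 discs, 260 records):

```
Recovery vs truth: bias -0.015 points, MAE 0.065 points
B0 recovery MAE across subjects: 0.0021 ppm (max 0.0023)

Age-corrected cohort means (95% CI):
   cohort     mean    lower    upper
1     AIS 2.936458 2.376890 3.496026
2 control 3.330188 2.966667 3.693709

Age-corrected region means (95% CI):
1     AF 2.362821 2.140892 2.584750
2     NP 3.994686 3.772758 4.216615

Total: 22 of 50 patient discs affected (44%)
```

i.e. the pipeline recovers the injected B0 field to ~0.002 ppm, each disc
record to ~0.07 points, the generative NP > AF ordering, and the exact
affected-disc bookkeeping (9/6/4/3/0 across L1/L2…L5/S1).

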