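---
title: "Methods: simulating and quantifying gagCEST imaging of lumbar discs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying gagCEST imaging of lumbar discs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagcest)
```

## The problem

Glycosaminoglycan (GAG) depletion is the earliest, still-reversible step of
intervertebral disc degeneration, preceding anything visible on morphologic
MRI. gagCEST imaging measures GAG content indirectly: a frequency-selective
saturation pulse applied near +1 ppm from water labels the hydroxyl protons
of GAG, which exchange with bulk water and depress the water signal. Scanning
the saturation offset ω yields a z-spectrum Z(ω) = S(ω)/S0, and the
magnetization-transfer-ratio asymmetry

MTRasym(Δω) = Z(−Δω) − Z(Δω)

isolates the exchange effect from (symmetric) direct water saturation. The
gag score of a voxel or region is 100 × the mean of MTRasym over the
GAG-specific band Δω = 0.9–1.9 ppm, reported in percent.

This package implements that analysis chain for a two-cohort lumbar-spine
study (adolescent idiopathic scoliosis patients vs healthy controls, five
discs L1/L2–L5/S1 per subject), together with a synthetic data generator
that renders the whole acquisition with known ground truth, so every stage
of the chain can be validated quantitatively.

## Generative model

### Lorentzian pool spectra

Tissue z-spectra are modelled as a sum of Lorentzian saturation lines,

Z(ω) = 1 − Σ_k A_k · L(ω − δB0; c_k, w_k),
L(x; c, w) = (w/2)² / ((w/2)² + (x − c)²),

with a direct water saturation pool (c = 0, FWHM 1.2 ppm, A = 0.85), a GAG
hydroxyl pool (c = +1.0 ppm, FWHM 0.5 ppm, amplitude calibrated), and an
optional broad symmetric magnetisation-transfer pool (c = 0, FWHM 20 ppm,
A = 0.05, off by default). We deliberately do not integrate Bloch–McConnell
equations: the acquisition's saturation parameters (B1, pulse duration) are
not part of the model's inputs, and the Lorentzian family admits a
*closed-form* band-averaged asymmetry,

score = 100 · mean over band of Σ_k A_k [L(Δω; c_k, w_k) − L(−Δω; c_k, w_k)],

implemented in `analytic_mtrasym()`. This oracle is what makes the pipeline
testable end to end: symmetric pools contribute exactly zero, and the score
is exactly linear in the GAG amplitude, so `calibrate_gag_amplitude()` can
invert it by a single division. Phantom regions are rendered with amplitudes
calibrated so their true scores equal prescribed percent values — including
the cohort means a study would report. The amplitudes are phenomenological:
no attempt is made to map them to exchange rates or concentrations.

### Phantom, B0 field and acquisition

`make_spine_phantom()` draws a mid-sagittal cartoon of the lumbar spine on a
188 × 188 grid with 1.6-mm pixels (300-mm field of view): six rectangular
vertebral bodies separated by five elliptical discs, each disc split into a
nucleus pulposus (NP) core and an annulus fibrosus (AF) rim. Because no
standard definition exists for the NP/AF boundary on CEST images, the same
rule is used in the generator and in the analysis: NP = pixels whose
distance-transform depth inside the disc is at or above the median positive
depth (configurable percentile). Disc positions get a small seed-controlled
jitter so subjects differ.

B0 inhomogeneity is a smooth random field: Gaussian white noise smoothed at
a 60-mm length scale and rescaled so max |δB0| equals the requested
amplitude (default 0.3 ppm — a realistic worst case for a 3 T spine exam;
all frequencies in ppm, with 1 ppm = 127.7 Hz at 3 T available as a constant
but never applied implicitly).

`render_subject()` produces raw stacks: CEST (31 offsets, −3…+3 ppm),
WASSR (21 offsets, −1…+1 ppm, rendered with a narrow low-power water line
only, FWHM 0.5 ppm, amplitude 0.7) and an unsaturated S0 image with
tissue-dependent intensity (NP brightest, AF intermediate, bone dark).
Noise is additive Gaussian on the *normalized* signal (default sd 0.01);
at the signal-to-noise ratio of normalized, ROI-averaged spectra the
Gaussian approximation to Rician noise is appropriate. Raw signals are
S0 × (Z + noise).

### Cohort generator

`cohort_design()` fixes the study conditions: 16 controls and 10 patients
(130 lumbar discs), generative cohort means 3.51% (control) and 2.76% (AIS)
with an NP−AF difference of 1.53 points, between-subject SD 0.6, residual SD
0.5 per disc × region, ages 25.5 ± 1.7 vs 18.3 ± 8.2 years, Pfirrmann
grade-3 frequencies of 1/80 and 2/50 (all other discs grade 2), Cobb angles
34.8 ± 21.5° truncated to 11–73°, and per-patient stable-vertebra levels
{L1×1, L2×3, L3×2, L4×1, L5×3}. True scores are cohort-region mean +
subject random intercept + residual; draws below 0 are truncated at 0 and
logged, and draws above the pool-model feasibility bound (≈6.1% with water
amplitude 0.85) are truncated there and logged — both rare (<1%) under the
defaults. True scores carry no age, gender or Pfirrmann effect, so the
age-corrected cohort means in truth equal the generative cohort means; the
covariates exist to exercise the model machinery, not to encode effects.

All randomness flows from one top-level integer seed through
`split_seed()`, a multiplicative-congruential child-seed scheme (seeds stay
below 2³¹); per-subject, per-stage streams are independent, which we
verified empirically (lag correlation ≈ 0 across 2000 streams, cohort-mean
deviations across 200 design seeds: mean −0.004, SD 0.206 vs 0.196
expected).

### What the generator does not emulate

Cartoon anatomy (no ligaments, vessels, cord, or curvature of the spine
itself), no motion or registration errors, no Rician noise floor, no B1
inhomogeneity, no partial-volume fat, and a Lorentzian rather than
Bloch–McConnell lineshape. Passing tests therefore demonstrate the
*correctness of the analysis chain* under controlled conditions — they do
not certify performance on clinical data, where motion correction and
acquisition fidelity dominate.

## Quantification chain

### B0 correction (WASSR maximum symmetry)

The water line's apparent center shifts with the local field. Each masked
voxel's WASSR spectrum is normalized and fed to `mscf_offset()`, which
minimizes the mirror-symmetry cost

C(δ) = mean over usable i of [Ẑ(2δ − ω_i) − Z(ω_i)]²,

where Ẑ is the natural-cubic-spline interpolant and "usable" restricts to
mirrored coordinates inside the sampled range (no extrapolation, ever).
Using the *mean* rather than the raw sum keeps candidates comparable when
their usable-pair counts differ; a raw sum would systematically favour
candidates near the search bound under noise, where fewer pairs survive.
Candidates with fewer than 5 usable pairs are excluded. The search runs on a
coarse grid (±0.5 ppm, 0.01-ppm steps), then a local 0.002-ppm grid, then
parabolic interpolation of the cost minimum; exact ties resolve toward the
smallest |δ|. On the default phantom the estimator is exact to <0.005 ppm
noiselessly and <0.01 ppm mean absolute error at noise sd 0.01; its error
grows monotonically with noise. Failed voxels are recorded with coordinates
and set missing — never silently zeroed.

### MTR asymmetry and gag score

`mtrasym_curve()` evaluates Z(−Δω) − Z(Δω) on the B0-corrected spectrum.
The shift and the band evaluation are composed into a single spline
evaluation Ẑ(±Δω + δB0) — mathematically identical to resampling the shifted
spectrum first (`zs_shift()` provides that contract) but avoiding a second
interpolation pass. The band is a fixed 11-point grid, 0.9 to 1.9 ppm in
0.1-ppm steps, endpoints inclusive; the quadrature grid is a package choice
(the band itself is standard), and evaluating on measured offsets only is
possible by passing those offsets as the band. Negative scores are retained
so cohort statistics stay unbiased; flooring at zero would bias sparse-cell
means upward.

Numerical accuracy: with 31 samples at 0.2-ppm spacing, natural-spline
interpolation of the narrow GAG line is the accuracy bottleneck. The
band-averaged error is ≈0.006 points at δB0 = 0 and stays below 0.05 points
for |δB0| ≤ 0.3 ppm — inside the oracle-equivalence tolerance used by the
tests; individual curve points stay within 5 × 10⁻⁴ of the analytic
asymmetry.

### Segmentation

A Gaussian naive Bayes voxel classifier (classes background / bone / disc;
features: S0 intensity, mean saturated signal normalized by S0, normalized
row and column position) is trained by maximum likelihood with per-class
variances floored at 10⁻⁶ of the pooled feature variance. The
implementation is vectorized for ~35 000-voxel images; a unit test
cross-checks its predictions against the reference Gaussian naive Bayes in
`e1071`. Disc-class voxels are split into connected components, components
are matched to the five segments by the vertical order of their centroids
(ties toward the larger component), and each disc is partitioned NP/AF by
the distance-transform rule above. A component count other than five flags
the ROI set "needs verification" instead of silently merging.
`verify_rois()` mirrors a reader's check: ROIs may be translated
("repositioned") but any size-changing edit is rejected, and a reference
label image yields a per-disc Dice report.

### Records and the linear mixed model

`summarize_discs()` averages the gag map over each ROI region, producing one
record per disc × region (260 records for the default design; empty regions
are logged and excluded). `fit_lmm()` fits, by REML, gag ~ cohort + region +
segment + age + gender + Pfirrmann + cohort:segment + cohort:region with a
subject random intercept (lme4/lmerTest); the interaction set is
configurable because the clinical analysis does not enumerate which
interactions entered, and cohort × segment plus cohort × region are the two
the reported tables require. Terms constant in the data (e.g. a single
observed Pfirrmann grade) are dropped with a message rather than fitted
rank-deficiently. Inference uses Satterthwaite degrees of freedom;
`corrected_means()` evaluates estimated marginal means at age 23.1 years,
averaging over the observed distribution of the other covariates
(proportional weights), with Wald 95% CIs and *unadjusted* pairwise
p-values (α = 0.05, exploratory; no multiplicity correction). The affection
analysis (affected = disc entirely proximal to the patient's stable
vertebra, i.e. its inferior adjacent vertebra at or above it; L5/S1 is never
affected for a lumbar stable vertebra) is fitted on patient NP records only,
since controls carry no affection status.

## Numerical and design choices worth knowing

- **Natural cubic splines** everywhere a spectrum is evaluated off-grid; no
  extrapolation under any circumstances — out-of-range queries raise errors
  that name the remedy (wider acquisition range).
- **Spectra are not clipped** to [0, 1]; noisy excursions are retained.
- **Tie-breaks** are deterministic: MSCF ties toward smallest |δ|,
  component matching toward larger area, NB toward the larger prior.
- **Determinism**: quantification has no randomness; re-running the pipeline
  on the same cohort writes byte-identical CSVs.
- **Degenerate inputs**: zero B0 amplitude gives an exactly zero field; zero
  variances reproduce generative means exactly; a zero random-intercept
  variance fits at the boundary and is flagged (singular), not hidden.
- **Problem sizes in the tests**: unit tests run on 96-pixel grids
  (~20-voxel ROIs) where the per-record noise floor is ≈0.1 points;
  study-level checks use the full 188-pixel acquisition geometry, a
  26-subject cohort for end-to-end recovery, 50 record-level replicate
  cohorts for CI coverage, and 10 rendered subjects for segmentation
  overlap. These sizes were chosen so the whole suite runs in a few minutes
  while keeping Monte-Carlo error well inside each tolerance.
- **Replicate averaging for cohort-level recovery**: one simulated
  26-subject cohort carries sampling noise of SD ≈0.2 points on each cohort
  mean (0.6 / √10 for the patient arm), so a single draw lands outside the
  target's CI for roughly one seed in twelve even though the pipeline is
  unbiased. The cohort-level recovery check therefore averages the
  age-corrected means over three independently seeded replicate cohorts,
  which tests pipeline bias rather than one cohort's luck.

## Known limitations

- The Lorentzian amplitudes are not physical exchange parameters; absolute
  agreement with Bloch–McConnell simulations or phantoms is out of scope.
- The age correction extrapolates the patient arm ≈5 years with a slope
  estimated mostly from between-subject variation; with 10 patients this is
  the largest variance contributor to the corrected AIS mean.
- The NP/AF boundary rule is a stand-in for an unreported clinical
  convention; changing `np_percentile` changes region means, which is why
  the generator and the analysis share the rule.
- Thoracic segments, motion, and registration are out of scope.
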