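---
title: "Activation network mapping: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation network mapping: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ANMtools)
```

## The method

Coordinate-based meta-analyses start from a corpus of studies that each
report a handful of activation peak coordinates in a standard stereotaxic
space. Activation network mapping asks a network-level question of those
peaks: rather than testing where peaks cluster, it asks which brain regions
are *functionally connected* to the reported peaks, using a large normative
resting-state connectome as the reference. The procedure implemented here
is, per group (autistic and neurotypical study samples):

1. **Coordinate normalisation.** All peaks are brought into MNI space.
   Talairach-tagged peaks are converted with a published affine (see below).
2. **Coactivation seeds.** For each study, a 6-mm-radius sphere (closed
   ball, Euclidean distance between world-coordinate voxel centers) is drawn
   around every reported peak, and the spheres of one study are unioned into
   a single binary *coactivation seed* — the per-study unit of all later
   inference.
3. **Seed-to-voxel connectivity.** For every connectome participant and
   every seed, the Pearson correlation between the seed's mean time series
   and each in-mask voxel's time series is Fisher z transformed
   ($z = \operatorname{atanh} r$), giving one z map per (participant,
   study).
4. **Overlap branch.** Within each study, the participant-level z values are
   tested against zero with a voxelwise one-sample $t$ test
   ($t = \bar z / (s/\sqrt{n})$, sample sd); the study map is binarised at
   a critical $t$ (strictly greater). A voxel enters the group's *overlap
   map* iff it is covered by strictly more than 60% of the group's
   study maps — with 18 studies, at least 11.
5. **t-map branch.** Within each study the participant z maps are averaged;
   across studies the experiment-level means are again tested against zero
   with a voxelwise one-sample $t$ (df = E−1) and thresholded at the same
   critical value.
6. **Contrast and similarity.** The two groups are contrasted (by default
   the set difference of the retained masks, in both directions), and each
   group's overlap and t maps are correlated over the brain mask as a
   closeness check between the two branches.

Peaks of the resulting maps are extracted and labelled against integer
atlases (AAL-style and Brodmann-style lookups) into plain TSV tables.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `radius` | 6 mm | sphere radius around each peak |
| `tThreshold` | 5.66 | fixed critical $t$ used at both statistical levels |
| `overlapFraction` | 0.60 | strict retention fraction for the overlap map |
| `thresholdMode` | `fixed_t` | or `alpha_derived`: $t$ from `qt(1 - α/2, df)` |
| `alpha` | 0.05 / in-mask voxels | voxelwise Bonferroni, used by `alpha_derived` |
| `contrastMode` | `set_difference` | or `proportion_test`, `two_sample_t` |
| `similarityOperands` | `unthresholded` | fraction vs raw t; or `binarized` |
| `excludeSeedVoxels` | `FALSE` | zero a seed's own voxels in its z maps |
| `clipR` | 1 − 10⁻⁷ | correlation clip before `atanh`, keeps z finite |

Three of these deserve comment, because the conventional method description
leaves them underdetermined and this package had to make the call:

* **The fixed threshold 5.66 at both levels.** The conventional chain
  "p < 0.05/285,903 voxels" does not reproduce 5.66 under a standard
  Student-t quantile at either level's df (with 1000 participants,
  `criticalT(0.05/285903, 999)` ≈ 5.26; with 18 experiments and df = 17 the
  value is far larger). The package therefore treats 5.66 as an opaque
  conventional constant by default and exposes `thresholdMode =
  "alpha_derived"` as the df-consistent alternative, so the discrepancy is
  auditable rather than hidden. Note also that 0.05/285,903 is
  1.7488 × 10⁻⁷ (sometimes printed rounded as 1.76 × 10⁻⁷).
* **"More than 60%" is strict.** `count/E > 0.60`, so with E = 18 a voxel
  needs 11 studies (10/18 = 55.6% fails, 11/18 = 61.1% passes). The helper
  `minRetainCount()` exposes this arithmetic.
* **Similarity operands.** Whether the overlap-vs-t-map correlation should
  be computed on thresholded or unthresholded maps is not fixed by the
  method description. The default correlates the unthresholded overlap
  *fraction* volume with the unthresholded *t* volume (the
  information-richer choice); `similarityOperands = "binarized"` switches to
  the retained/thresholded masks. The choice is recorded in the run
  manifest either way.

Two further open choices were resolved as follows. Seed voxels are
*included* in their own connectivity maps by default (their self-correlation
is informative for overlap with the seed region), with a flag to exclude
them. And the group contrast defaults to the set difference of retained
masks — the weakest assumption consistent with reporting "peaks of comparing
one network with the other" — with inferential modes (two-proportion z on
overlap counts; voxelwise Welch t on experiment-level mean z) available when
an error-controlled contrast is wanted.

## Coordinate conversion

Talairach-to-MNI conversion uses the Lacadie et al. (2008) "mni2tal" affine
as the default: the published 4×4 MNI→TAL matrix is inverted exactly, so
`talToMni()` and `mniToTal()` are exact functional inverses. The Brett
(1999) piecewise transform (separate linear maps above and below z = 0,
branch chosen by the sign of the input z) is available as
`method = "brett"`; being piecewise, it is only approximately self-inverse
near the boundary plane. Tests assert round-trip and independent
matrix-oracle properties rather than fixed coordinates.

## Geometry conventions

World coordinates are RAS+ mm; any input NIfTI not already RAS+ is
reoriented on load (and the reorientation reported). Voxel indices are
0-based; sphere membership and peak distances are always computed in world
mm so anisotropic grids behave correctly; `worldToVoxelNearest()` rounds
half away from zero for determinism. All volumes of a run must share one
grid — a mismatch is an error, never a silent resample. Out-of-mask voxels
are stored as 0 with the mask carried separately, so no NaN can leak into
overlap counts; zero-variance voxels yield $t = 0$ (counted and reported),
never NaN.

## The synthetic connectome

Real normative connectomes (the reference deployment uses a 1000-participant
resting-state cohort) cannot ship with a package, so validation runs on a
synthetic stand-in with planted ground truth, generated by
`simulateConnectome()` / `simulateFoci()` from a `SyntheticSpec`:

* Networks are axis-aligned voxel blocks. Every voxel of network $k$ shares
  a latent time series $\ell_k \sim N(0, \sigma_s^2)$ plus i.i.d. noise
  $N(0, \sigma_n^2)$, so the expected within-network correlation is
  $\rho = \sigma_s^2 / (\sigma_s^2 + \sigma_n^2)$ and cross-network
  correlations vanish in expectation. Blocks rather than anatomical shapes
  keep the ground truth exact; no pipeline stage requires contiguity.
* Study foci are drawn uniformly from their target network's voxel centers,
  assigned round-robin when a study targets several networks, jittered
  uniformly in a ball (≤ `fociJitterMm`) and clamped into the mask.
* Every participant and every study consumes its own RNG substream derived
  from the master seed, so the simulation is bit-reproducible and growing
  the roster leaves earlier entities untouched.

The default conditions (`defaultSyntheticSpec()`) are a 24×24×24 grid at
4 mm, 24 participants × 120 timepoints, three disjoint 4×4×4-voxel networks
A, B, C with $\sigma_s = \sigma_n = 1$ (ρ = 0.5, a strong but realistic
within-network coupling), and 18 studies per group with 3 foci each and
2 mm jitter — mirroring the 18-study corpus of the motivating analysis
while remaining computable in well under a minute on one CPU. Every
neurotypical study targets networks A and B; every autistic-group study
targets A only; C is planted but untargeted. The expected answer key
(`groundTruth()`) is then: NT retained = A ∪ B, ASD retained = A,
NT-minus-ASD = B, ASD-minus-NT empty, with C probing false positives.

What the simulator deliberately does **not** emulate: hemodynamic
autocorrelation, participant motion, spatial smoothness of noise,
anatomical network shapes, or between-participant variability in network
topography. Passing recovery tests therefore demonstrates that the
*pipeline arithmetic* is correct and well calibrated under its stated
model — not that the method is robust to the physiological confounds of
real resting-state data.

## Validation design

```{r, eval = FALSE}
spec <- defaultSyntheticSpec(rngSeed = 1)
cfg  <- anmConfig(rngSeed = 1)
sim  <- simulateConnectome(spec)
foci <- simulateFoci(spec)
nt   <- runGroup(foci, sim$participants, sim$mask, "NT",  cfg)
asd  <- runGroup(foci, sim$participants, sim$mask, "ASD", cfg)
cmp  <- runCompare(nt, asd, sim$mask, cfg)
gt   <- groundTruth(spec, cfg)
dice(nt$overlap@retained, gt@expectedRetained$NT)
```

The test suite checks, among others: exact sphere voxelisation against an
exhaustive lattice enumeration (a 6-mm sphere on a 2-mm grid holds exactly
123 voxels); the strict overlap arithmetic (minimal retaining count 11 of
18); exact agreement of the t, overlap, group-map and contrast stages with
brute-force per-voxel loop oracles on random 10³ volumes; simulator
calibration (mean within-network correlation 0.5 within 3·SE on the Fisher
z scale, SE = $1/\sqrt{T-3}$, at T = 200); full-pipeline parameter recovery
(per-group Dice ≥ 0.9 against the planted masks; contrast sensitivity
≥ 0.8 and false-discovery proportion ≤ 0.1); monotonicity of all retained
masks in the threshold and the overlap fraction; and end-to-end determinism
(byte-identical NIfTI outputs on rerun). Problem sizes (10³ oracle grids,
the 24³ default world, T = 200 calibration runs) were chosen so the whole
suite runs in well under a minute while keeping the Bonferroni-style
threshold meaningfully strict.

## Known limitations

* The headline anatomical outputs of the motivating analysis (peak tables
  in thalamus, caudate, precuneus, etc., and the printed overlap-vs-t
  similarities 0.65/0.45) depend on the real 1000-participant connectome
  and are not reproducible from synthetic data; this package reproduces the
  *procedure* and validates it on planted ground truth.
* No cluster-extent correction, FDR, or permutation inference — the method
  is defined with a fixed voxelwise threshold only.
* The t-map branch treats experiments as independent samples, but all
  experiments share the same connectome participants, so the
  across-experiment variance is deflated and the thresholded t map is
  permissive wherever seeds overlap. This is a property of the method
  itself, inherited faithfully here; quantitative recovery claims in the
  validation suite rest on the overlap branch.
* No resampling between grids: inputs must share one lattice.
* The piecewise Talairach transform is not exactly invertible at the
  z = 0 boundary; the affine default is.
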