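---
title: "Two-step epileptogenic zone detection from diffusion kurtosis maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step epileptogenic zone detection from diffusion kurtosis maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrark)
```

## The problem and the model

In surgical candidates with drug-resistant epilepsy and inconclusive routine
MRI, the epileptogenic zone (EZ) must be localised from indirect evidence.
Diffusion MRI contributes a tissue-microstructure signature: epileptogenic
tissue tends to show increased mean diffusivity (MD), reduced fractional
anisotropy (FA) and reduced mean kurtosis (MK). `idrark` turns that
signature into a two-step, single-subject detection procedure. Everything
operates on co-registered 3-D parametric maps (MD in µm²/ms, FA and MK
dimensionless) for one patient and a control group on a common voxel grid;
tensor fitting, spatial normalisation and smoothing are upstream of this
package and assumed done.

### Step one: lobar asymmetry

A deep white-matter skeleton is built from the cohort-mean FA map. Healthy
white matter is strongly left–right symmetric, so each metric is sampled at
mirrored voxel pairs and summarised as an asymmetry index per pair,
`AI = (right − left)/(right + left)`. AI is dimensionless, antisymmetric
under hemisphere swap, bounded by (−1, 1) for positive inputs, and invariant
to global rescaling — which is why the pipeline is insensitive to the units
of MD.

The patient's AI map is compared with the controls' by a one-tailed general
linear model per pair (intercept, patient indicator, sex, age; t is the
patient coefficient over its standard error with n − 4 degrees of freedom).
Both directions are tested, because either sign of asymmetry is
diagnostically meaningful: increased MD asymmetry implicates the right
hemisphere, increased FA/MK asymmetry the left, and vice versa. Family-wise
error is controlled by a permutation max-statistic test on TFCE-enhanced
t-maps at α = 0.05. Surviving voxels (connected clusters of at least 20
voxels) are aggregated per lobe as the lobar asymmetry index LAI =
significant voxels / skeleton voxels of the lobe, and the (lobe, hemisphere)
with the highest LAI is selected.

### Step two: the iDrArK overlap map

Voxel-wise one-tailed t-maps against the control group (same GLM) are
binarised at uncorrected p < 0.001 — MD testing for increase, FA and MK for
decrease — and intersected. Requiring all three directions concurrently is
the core of the method: each single-metric map is noisy and widespread, but
their conjunction is spatially specific. Clusters smaller than 20 voxels are
removed. When step one was significant the map is restricted to the selected
lobe (and the size filter re-applied, since the minimum cluster size is a
property of final maps); otherwise the whole-brain map is used, so patients
without a lobar result are not excluded.

### Evaluation against resection

Detection maps are scored against the surgical resection zone dilated by
10 mm (eRZ; the dilation absorbs postsurgical brain shift). Per subject,
PPV = clusters majority-inside the eRZ / all clusters; subjects are
classified SD (PPV ≥ 0.5), UD (PPV < 0.5) or NS (no clusters). Per cohort,
accuracy = SD/(SD+UD) and detection rate = (SD+UD)/(SD+UD+NS). The same
machinery evaluates single-metric maps and pairwise overlaps, and compares
the one-step (unrestricted) with the two-step (lobe-restricted) procedure on
the subgroup of patients with a significant lobar result.

## Tunable parameters

All constants live in `idrark_config()`; defaults reproduce the published
protocol.

| parameter | default | meaning |
|---|---|---|
| `fa_skeleton_threshold` | 0.2 | mean-FA cutoff defining the WM/GM border; higher values push the skeleton deeper |
| `voxelwise_p` | 0.001 | uncorrected one-tailed threshold for volume t-maps |
| `fwe_alpha` | 0.05 | FWE level of the skeleton permutation test |
| `min_cluster_voxels` | 20 | clusters below this size are discarded everywhere |
| `erz_dilation_mm` | 10 | resection-zone dilation radius (mm) |
| `ppv_success_threshold` | 0.5 | PPV at or above which a subject counts as SD |
| `n_permutations` | exhaustive | label reassignments; capped at N − 1 for N subjects |
| `tfce_E`, `tfce_H` | 0.5, 2 | TFCE extent and height exponents (standard published defaults) |
| `tfce_dh` | max/100 | TFCE integration step, adaptive per enhanced map |
| `cluster_connectivity` | 26 | neighbourhood for clusters and TFCE extents |

## Numerical and design choices

**Permutation scheme.** With a single patient, the only exchangeable unit is
which subject carries the patient label. Covariates are handled
Freedman–Lane style: the response is residualised on the nuisance-only model
and the patient's residual row is swapped with each reassigned subject's row
before refitting. The corrected p-value uses the add-one estimator
`p(v) = (1 + #{perm max ≥ obs(v)})/(1 + n_perm)`, so p never reaches zero and
with exhaustive reassignment over N subjects the attainable floor is 1/N.
Consequence worth knowing: significance at α = 0.05 requires at least 21
subjects; with 101 subjects the floor is ≈ 0.0099.

**TFCE.** Implemented as the Riemann sum
`TFCE(v) = Σ_h extent(v, h)^E · h^H · dh` over thresholds `h = dh, 2dh, …`,
with connected components in C++. On a constant blob of n voxels at height
h0 this converges to `n^E · h0^(H+1)/(H+1)`; the test suite checks the sum
against that closed form and its O(dh) convergence. Each enhanced map uses
its own step `max/100`, the convention of the reference implementation.

**Skeleton.** A full TBSS reimplementation (nonlinear template registration,
perpendicular max-FA projection search) is out of scope. The skeleton here
is the medial core of the thresholded cohort-mean-FA mask: voxels in the
deepest half of the erosion-depth transform that are a local depth maximum
along at least one axis, symmetrised by intersection with the mirror image
about the mid-plane between the two central sagittal slices (exact on
even-width grids). Metric values are sampled directly at skeleton voxels.
On smooth co-registered maps this preserves the method's logic; for real
data a precomputed skeleton mask can be passed via the `skeleton_mask`
argument. Degenerate voxel pairs with `right + left = 0` abort rather than
return 0: on physical maps both values are positive, so a zero sum indicates
a masking bug.

**Cluster conventions.** 26-connectivity throughout (on the thin skeleton a
stricter neighbourhood fragments genuine clusters); the minimum-size filter
is applied per (lobe, hemisphere) cell in the lobar step. LAI argmax ties are
broken by surviving voxel count, then lobe name, then hemisphere —
deterministic output was preferred over any substantive claim about ties.
A cluster counts as "within" the eRZ when the majority (> 50%) of its voxels
lie inside: any-overlap would inflate the count, full containment would
punish boundary clusters.

**Grids.** Voxel indices are 1-based arrays in R, world coordinates follow
the NIfTI affine, and the left–right axis is the first array dimension with
an even extent so a mirror plane exists between the two central slices.
Grid or affine mismatches are hard errors; nothing is silently resampled,
because resampling would corrupt the mirrored voxel pairing.

## The synthetic cohort generator

`make_phantom_anatomy()` builds an ellipsoidal brain (default 40×48×40
voxels at 2 mm — the acquisition resolution the protocol targets, which also
makes the 10 mm dilation an exact 5-voxel ball), a mirror-symmetric atlas of
angular-sector "lobes", and a deep-WM mask. `simulate_control()` produces
smooth, approximately symmetric fields: FA ≈ 0.45 in deep WM tapering below
0.2 at the edge, MD ≈ 0.8 µm²/ms, MK ≈ 1.0, each modulated by a
Gaussian-smoothed subject-specific field (coefficient of variation 3%, the
lower end of a realistic 3–5% inter-subject band) plus 1% voxel noise.
Smoothness is produced by Gaussian filtering of white noise with a ~2-voxel
kernel, standing in for the smoothed maps the upstream pipeline would
deliver. Ages are drawn from 22–36 years so the covariate code paths are
exercised; demographics carry no planted effect.

`simulate_patient()` starts from the control draw of the same seed and
multiplies MD by (1+δ), FA by (1−δ) and MK by (1−δ) inside a lesion ball
with a cosine edge taper, optionally adding a widespread lobar deep-WM MK
reduction; lesion deltas default to 0.2 and the lobar reduction to 0.25,
within the 10–30% band chosen for testability (the clinical literature does
not pin down effect sizes for this population). The resection zone returned
is the lesion ball itself.

What the phantom does *not* emulate: cortical folding, genuine fibre
geometry (so FA anisotropy structure is absent), registration error,
scanner-specific artefacts, and pathology heterogeneity. Passing tests on
phantoms therefore demonstrate the statistical machinery — calibration,
power against planted effects, bookkeeping — not clinical performance.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at these sizes, chosen as
the smallest that keep the checks meaningful: planted-lobe and
planted-lesion recovery on 30-control cohorts at the full 40×48×40 grid over
10 seeds each; permutation type-I error on 200 null cohorts of 20 controls
plus one null patient at 24×28×24 (21 subjects put the exhaustive
permutation floor at 1/21 < 0.05, so rejections are possible and the
empirical rate can be compared with α within binomial error). The published
accuracies and detection rates are reproduced exactly from the shipped
clinical classification counts through the same evaluation functions used
everywhere else.

## Known limitations

* The skeleton is a geometric simplification; on real data, supply a
  TBSS-derived skeleton mask for fidelity to the reference pipeline.
* One patient vs. group permutation caps the attainable significance at 1/N;
  small control groups cannot yield FWE-significant asymmetries.
* The analysis brain mask for the voxel-wise step is an input; the package
  does not derive tissue-specific masks.
* Lobe assignment of skeleton voxels uses the atlas label at the voxel
  (nearest non-background label as fallback); sub-lobar parcellations are
  out of scope.
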