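# idrark

Two-step detection of the epileptogenic zone (EZ) from diffusion tensor and
kurtosis parametric maps, for single patients compared against a healthy
control group.

Routine MRI is inconclusive in a substantial share of surgical epilepsy
candidates. Diffusion MRI offers a way in: epileptogenic tissue tends to show
**increased mean diffusivity (MD)**, **reduced fractional anisotropy (FA)**
and **reduced mean kurtosis (MK)**. `idrark` implements a detection pipeline
built on exactly that signature:

1. **Lobe-level detection.** A symmetric deep white-matter skeleton is built
   from the cohort-mean FA (WM/GM border at FA = 0.2). Each metric is sampled
   at mirrored voxel pairs and reduced to an asymmetry index per pair,

   $$AI_{vx} = \frac{right_{vx} - left_{vx}}{right_{vx} + left_{vx}},$$

   tested one patient vs. controls with one-tailed permutation tests
   (sex and age as nuisance covariates), threshold-free cluster enhancement
   (TFCE) and max-statistic family-wise-error correction at p < 0.05.
   Significant voxels (clusters < 20 voxels removed) are aggregated per lobe
   into the **Lobar Asymmetry Index**
   $LAI_{LOBE} = N_{vx}(p_{FWE}<0.05)_{LOBE} / N_{vx\,LOBE}$, with the
   impaired hemisphere attributed from the asymmetry direction (increased MD
   asymmetry → right hemisphere; increased FA/MK asymmetry → left, and vice
   versa). The lobe with the highest LAI wins.

2. **Voxel-level detection (iDrArK).** One-tailed voxel-wise t-maps (MD up,
   FA down, MK down; uncorrected p < 0.001) are binarised and intersected;
   clusters < 20 voxels are removed. If step one was significant, the map is
   restricted to the detected lobe; otherwise the whole-brain map is used.

3. **Evaluation.** Maps are scored against the surgical resection zone
   dilated by 10 mm (eRZ): per subject
   $PPV = NC_{eRZ}/NC$ (clusters majority-inside the eRZ over all clusters),
   classified SD (PPV ≥ 0.5), UD (PPV < 0.5) or NS (no clusters); per cohort
   $accuracy = SD/(SD+UD)$ and $detection\ rate = (SD+UD)/(SD+UD+NS)$, for
   iDrArK as well as single-metric and pairwise-overlap maps.

A fully synthetic cohort generator (ellipsoidal phantom, mirror-symmetric
lobe atlas, smooth subject-specific fields, plantable focal lesions and
widespread lobar MK reductions) makes every stage testable without clinical
data.

## Worked example

```r
library(idrark)

anatomy <- make_phantom_anatomy()           # 40 x 48 x 40 voxels at 2 mm
lesion  <- lesion_spec(center = c(28, 34, 26), radius_mm = 8,
                       delta_md = 0.2, delta_fa = 0.2, delta_mk = 0.2,
                       lobar_mk_decrease = list(lobe = "lobe03",
                                                hemisphere = "right",
                                                delta = 0.25))
cohort <- simulate_cohort(anatomy, n_controls = 30,
                          lesions = list(pat001 = lesion), seed = 42)
print(cohort)
result <- detect_patient(cohort, "pat001")
print(result$lobar)
print(result$maps_restricted$iDrArK)
print(result$detection$iDrArK)
```

prints

```
idrark cohort: 30 controls, 1 patients, grid 40x48x40 @ 2x2x2 mm
  resection zones: 1; atlas regions: 8
MK-LAI [pat001]: selected lobe03 (right), max LAI = 1.000
detection map (MD+FA+MK) [pat001]: 1 clusters, 158 voxels, restricted to lobe03 (right)
iDrArK [pat001]: 1/1 clusters in eRZ, PPV = 1.00 -> SD
```

The patient carries an 8 mm focal lesion (MD +20%, FA −20%, MK −20%) plus a
25% MK reduction across the deep white matter of its lobe. The MK lobar
asymmetry step selects that lobe (every skeleton voxel in it is significant,
LAI = 1.0); the lobe-restricted iDrArK map contains a single 158-voxel
cluster that falls inside the extended resection zone, so the detection is
classified successful with PPV 1.0.

Real cohorts are read from a CSV manifest plus NIfTI volumes with
`read_cohort()`; `run_idrark()` scores all methods over all patients. A thin
command-line wrapper with subcommands `simulate`, `skeleton`, `test`, `lai`,
`ez`, `evaluate` and `run` lives at `inst/cli/idrark.R`:

```sh
Rscript inst/cli/idrark.R simulate --out cohort/ --seed 5 --n-controls 30
Rscript inst/cli/idrark.R run --cohort cohort/ --out results/
```

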