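# odfreweight

Diagnosis and correction of anterior–posterior orientation bias in
diffusion-MRI fiber orientation distribution functions (fODFs), for
researchers mapping white-matter pathways that probabilistic
tractography systematically misses.

## The problem and the method

In deep white matter where a dominant anterior–posterior (A–P) bundle
crosses a thin medial–lateral (M–L) pathway, the fODF probability mass
is so skewed toward the A–P axis that trackers almost never sample the
M–L orientation: the pathway becomes a false negative even though its
signal is present.  The package implements:

- **The orientation angle φ** — for a direction `d = (x, y, z)` (RAS
  axes) with axial projection `d' = (x, y)`, φ is the signed angle
  between `d'` and the medial–lateral axis: φ = 0° on the A–P axis
  (A/P-symmetric), φ = −90° on the rightward and +90° on the leftward
  half of the M–L axis.  Density at |φ| ≈ 90° is M–L-oriented mass.
- **Cross-subject variance reweighting** — with aligned subjects, the
  per-(voxel, direction) cross-subject standard deviation σ(v, d)
  (ddof = 1) is low where the orientation signal is consistent across
  subjects.  Each subject's field is corrected inside an ROI as

  ```
  f̃_s(v, d) = f_s(v, d) / (σ(v, d) + ε)
  ```

  boosting reliable (presumed axonal) directions relative to
  subject-variable (presumed noise) ones.
- **Change histograms** — 20-bin histograms of φ over the directions
  with above-median probability increases and below-median decreases
  after reweighting, averaged across subjects: the correction's
  directional signature (decrease at 0°, increase at ±90°).
- **A minimal tracker** — bidirectional deterministic/probabilistic
  propagation with a 30° turning-angle constraint, tissue-threshold
  stopping (GM = valid termination, CSF = discard), six random seeds
  per seed voxel, bit-stable under its RNG seed.
- **Streamline density statistics** — per-voxel fraction of valid
  streamlines (set semantics, exact DDA segment traversal), target-ROI
  shares, and WM-normalized ROI densities.
- **A synthetic multi-subject phantom** — a WM slab carrying a dominant
  A–P bundle, a weak M–L bundle in a corridor between a medial seed
  wall and a lateral target wall (consistent across subjects), spurious
  per-voxel orientation kernels and a truncated-Gaussian floor that
  vary across subjects, plus tissue maps and masks — so the full
  suppression-and-recovery experiment runs from nothing.

See the methods vignette (`vignettes/reweighting-methods.Rmd`) for the
model, parameter defaults and design rationale.

## Worked example

```r
library(odfreweight)

params <- phantom_params(master_seed = 7)      # 20 subjects, defaults
ph <- generate_cohort(params)
#> <phantom_cohort> 20 subjects on grid 24x24x12
#>   corridor (reweighting ROI): 864 voxels; seed ROI: 48 voxels

rw <- reweight_cohort(ph$cohort)               # sigma + division, corridor ROI

# how much orientation mass sits within 9 degrees of the M-L axis?
mean(sapply(1:20, function(i)
  band_mass_fraction(cohort_subject(ph$cohort, i), ph$masks$deep_wm)))
#> 0.094   (before reweighting)
mean(sapply(1:20, function(i)
  band_mass_fraction(cohort_subject(rw$cohort, i), ph$masks$deep_wm)))
#> 0.128   (after)

# where did probability move?
change_histogram(lapply(1:20, function(i) cohort_subject(ph$cohort, i)),
                 lapply(1:20, function(i) cohort_subject(rw$cohort, i)),
                 roi_mask = ph$masks$deep_wm)
#> <change_histogram> 20 bins on [-90, 90] deg
#>   modal increase bin: [81, 90] deg
#>   modal decrease bin: [0, 9] deg

# does tracking now reach the lateral target?
tp <- tracking_params(rng_seed = 7)
seeds <- seed_points(ph$masks$seed_roi, tp, ph$cohort$affine)
ss_b <- propagate(cohort_subject(ph$cohort, 1), ph$tissue, seeds, tp)
ss_b
#> <streamline_set> 288 streamlines (step 0.5 mm)
#> valid_gm_termination        discarded_csf      discarded_angle
#>                   50                  235                    0
#>     discarded_length discarded_degenerate
#>                    0                    3
ss_a <- propagate(cohort_subject(rw$cohort, 1), ph$tissue, seeds, tp)
f <- function(ss) fraction_reaching_target(ss, ph$masks$target_lateral) *
  mean(ss$status == "valid_gm_termination")
c(before = f(ss_b), after = f(ss_a))
#> before  after
#>  0.066  0.115
```

Reading the numbers: before correction, only 9.4% of the corridor's
orientation mass lies within 9° of the M–L axis and 6.6% of seeded
streamlines validly connect the medial seed to the lateral target; after
dividing by the cross-subject standard deviation, the M–L mass fraction
rises to 12.8%, probability has moved from the A–P axis (modal decrease
bin straddling 0°) to the M–L axis (modal increase bin touching 90°),
and the seed-to-target connection rate nearly doubles.

## Command line

A thin Rscript front end ships in `inst/cli/odfreweight` with
subcommands `phantom`, `reweight`, `angles`, `track`, `density`,
`hist`; every run writes its effective configuration, package version
and input checksums next to its outputs.

```sh
Rscript inst/cli/odfreweight phantom --out-dir out/phantom --seed 1
Rscript inst/cli/odfreweight reweight \
    --fodf out/phantom/sub-01_fodf.nii.gz,out/phantom/sub-02_fodf.nii.gz,... \
    --roi out/phantom/mask_deep_wm.nii.gz --out-dir out/reweighted
```

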