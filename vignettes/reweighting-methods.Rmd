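---
title: "Cross-subject variance reweighting of fiber orientation distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject variance reweighting of fiber orientation distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odfreweight)
```

## The problem

Probabilistic tractography samples step directions from per-voxel fiber
orientation distribution functions (fODFs).  In deep white matter where a
dominant anterior–posterior (A–P) bundle crosses a much thinner
medial–lateral (M–L) pathway, the fODF probability mass is so skewed
toward the A–P axis that the M–L orientation is practically never
sampled: the thin pathway is a *false negative* of tractography, even
though its orientation signal is present in the data.  The pathways
between the anterior cingulate and the insula / ventrolateral prefrontal
cortex — running medial–laterally through the extreme capsule underneath
the large longitudinal bundles — are the motivating example.

This package implements a diagnostic statistic for this bias, a
correction based on cross-subject variance, the histogram summaries that
visualize what the correction changes, a minimal streamline tracker with
tissue-based stopping, streamline-density summaries, and a synthetic
multi-subject phantom on which the whole chain is reproducible without
any external data.

## The orientation angle φ

For a direction $d = (x, y, z)$ in RAS world axes (+x right, +y
anterior, +z superior), let $d' = (x, y)$ be its axial projection.  The
orientation angle is the signed angle between $d'$ and the M–L axis,
parameterized so that

* $\varphi = 0°$ when $d'$ lies on the A–P axis (either half — the
  statistic is A/P symmetric),
* $\varphi \to -90°$ as $d'$ rotates toward the right half of the M–L
  axis, and
* $\varphi \to +90°$ toward the left half.

Hence $\varphi \in [-90°, 90°]$, $\varphi(-d) = -\varphi(d)$, and
$|\varphi| \approx 90°$ flags M–L-oriented density.  When $d$ is
(numerically) parallel to the superior–inferior axis, $\|d'\| \le
10^{-8}\|d\|$, the angle is undefined; such directions carry an explicit
`NA` and are excluded from every histogram with a logged count rather
than silently dropped.

```{r phi}
orientation_angle(c(0, 1, 0))    # anterior-posterior
orientation_angle(c(1, 0, 0))    # rightward medial-lateral
orientation_angle(c(-1, 1, 0))
```

## Direction sets

All subjects share one antipodally symmetric set of 362 unit vectors
(181 pairs), placed by a deterministic electrostatic-repulsion descent
from a seeded start and shipped as a versioned TSV fixture
(`inst/extdata/sphere362.tsv`).  Freezing the set matters because the
reweighting below divides *per direction index* across subjects; any
per-subject re-ordering or re-optimization would silently break that
correspondence.  `build_sphere()` reproduces the fixture bit-exactly.

## Cross-subject variance reweighting

For a cohort of $S \ge 2$ subjects with aligned grids, let
$f_s(v, d)$ be subject $s$'s fODF density at voxel $v$ and direction
$d$.  The cross-subject sample standard deviation (ddof = 1)

$$\sigma(v, d) = \mathrm{sd}_s\, f_s(v, d)$$

is low where the orientation signal is consistent across subjects — the
signature of a real fiber population — and high where it is driven by
noise or by anatomically variable structure.  The corrected field is

$$\tilde f_s(v, d) = \frac{f_s(v, d)}{\sigma(v, d) + \varepsilon}$$

inside a chosen region of interest, leaving other voxels untouched.
Directions that are reliable across the cohort are boosted relative to
directions that fluctuate; in the crossing-fiber scenario this
specifically rescues the weak-but-consistent M–L peak relative to both
the dominant A–P peak (whose amplitude varies across subjects in
proportion to its size) and to spurious noise peaks (which vary
entirely).

Choices a user should know about:

* **σ convention** — `"voxelwise"` (default) computes σ per
  (voxel, direction) cell and assumes voxel correspondence across
  subjects; `"roi_pooled"` pools all ROI voxels and computes one σ per
  direction, which is defensible when nearby voxels carry similar
  orientation content and exact voxel correspondence is doubtful.  The
  mode is recorded in the result.
* **Guard ε** — default $10^{-8} \times \mathrm{median}(\sigma)$ over
  the ROI: scale-free, and only present so cells where all subjects
  agree exactly do not divide by zero.  With `epsilon = 0` and an
  exact-agreement cell, the operation refuses and names the voxel.
* **No renormalization** — the stored reweighted field is the plain
  quotient; probability normalization happens only inside
  `fodf_to_pmf()` when the tracker (or any consumer) needs a sampling
  distribution.
* **The ROI is a parameter** — σ estimation and reweighting apply
  inside a caller-chosen mask; on the phantom the natural choice is the
  deep-WM corridor where the bundles cross.

## Change histograms

To see *where on the sphere* the correction adds and removes
probability, `change_histogram()` compares per-voxel probability values
(each voxel's densities normalized to sum 1 — the raw quotient lives on
a different scale, so differencing raw fields would register an almost
uniformly positive change).  Per subject, reweighted-minus-original
differences are pooled over ROI voxels and directions, split into a
positive and a negative pool, and thresholded at each pool's median
(strictly above / strictly below, so median ties are never
double-counted).  The φ angles of the selected directions are binned
into 20 equal bins on $[-90°, 90°]$ and the per-bin counts are averaged
across subjects.  On the phantom, the modal decrease bin straddles 0°
(the A–P peak loses probability) and the modal increase bin touches
±90° (the M–L peak gains) — the directional signature of the
correction.  An empty pool (e.g. `after` identical to `before`) yields
an all-zero histogram and a flag, not an error.

## The tracker

`propagate()` is a deliberately minimal implementation of
anatomically constrained streamline propagation, sufficient to measure
connectivity recovery on the phantom:

* bidirectional tracking from every seed; the initial axis is sampled
  from the seed voxel's full fODF pmf (argmax in deterministic mode),
  then both hemispheres are tracked and concatenated;
* per step, candidate directions are restricted to the cone within
  `max_angle_deg` (default 30°) of the incoming direction — a sharper
  turn would discard the streamline, so the constraint is enforced by
  construction; deterministic mode takes the largest admissible
  density, probabilistic mode samples the admissible pmf;
* trilinearly interpolated tissue fractions stop a half *validly* when
  GM exceeds `gm_stop` (0.5) and discard the streamline when CSF
  exceeds `csf_stop` (0.5); a zero-density voxel discards it as
  degenerate; the step budget (or leaving the volume) discards it for
  length;
* fODF lookup is nearest-voxel: interpolating 362-direction densities
  buys little at phantom scale and would dominate the cost;
* the step size defaults to half the smallest voxel edge; six seeds per
  voxel are drawn uniformly inside each seed-mask voxel.

Both modes are bit-stable given `rng_seed`.  Backtracking-style
anatomical constraint (particle filtering) is intentionally out of
scope; threshold stopping preserves the same termination semantics at
phantom scale.

## Streamline density

`streamline_density()` counts, per voxel, the fraction of valid
streamlines that traverse it, with set semantics (a streamline counts a
voxel once however often it re-enters) and exact segment–voxel
traversal via a 3-D digital differential analyzer, so fast-moving
segments cannot skip voxels.  `roi_share()` normalizes mean densities
over a set of target masks; `wm_normalized_density()` divides an ROI's
mean density by the whole-WM mean (any log transform for statistics is
left to the caller); `direction_fractions()` and
`bundle_overlap_fractions()` summarize template direction weights and
bundle occupancy within an ROI.

## The phantom

`generate_cohort()` builds a multi-subject scene with known truth on a
24×24×12 mm grid (1 mm isotropic): a CSF shell, GM walls at the medial
and lateral faces, a WM slab between them, and an 8×6-voxel M–L
corridor box running the full width of the slab.  Seeds sit in the
first WM layer of the corridor next to the medial wall; the lateral GM
wall section facing the corridor is the target.

Per WM voxel and subject, the orientation density is

$$f_s(v, d) = a_{AP}\, g^{AP}_s K(d;\hat y) \;+\;
  a_{ML}\, g^{ML}_s\, w(v)\, K(d;\hat x) \;+\;
  \sum_{k=1}^{3} a_{v,k,s} K(d;\xi_{v,k,s}) \;+\; \epsilon_s(v,d)$$

with the following ingredients and defaults:

* $K(d;\mu) \propto \exp(\kappa((d\cdot\mu)^2 - 1))$, an antipodally
  symmetric Watson-type kernel with $\kappa = 20$, normalized to unit
  mean over the 362 directions so that amplitudes are total orientation
  mass.  (Normalizing to unit peak instead would let the additive noise
  floor carry more than half of each voxel's mass, which no real fODF
  does.)  The A–P bundle has $a_{AP} = 1$ everywhere in WM; the M–L
  bundle has $a_{ML} = 0.15$ inside the corridor indicator $w(v)$.
* $g^{AP}_s, g^{ML}_s \sim N(1, 0.1^2)$ (truncated at 0.05): per-subject
  bundle amplitude factors, i.e. ~10% inter-subject anatomical
  variability.  This is the ingredient the correction exploits: it makes
  cross-subject σ scale with bundle amplitude, so the dominant peak is
  damped proportionally more than the faint consistent one.  With the
  noise floor at $\tau = 0.15$ the M–L peak (density ≈ 2.2) sits in the
  flat-σ regime and is boosted ∝ its density, while the A–P peak
  (density ≈ 15) sits in the proportional-σ regime and is suppressed —
  which is also why the probability increase concentrates *at* ±90°
  rather than on the flanks.
* three spurious kernels per **voxel** and subject, axes uniform on the
  sphere, amplitudes uniform on $[0, 0.3]$ — individual noise peaks up
  to twice the true M–L bundle, confusable with it in any single
  subject.  Axes are drawn per voxel because spurious fODF peaks in
  real reconstructions decorrelate over space; a single phantom-wide
  kernel per subject would make σ depend on 60 global draws whose
  placement noise never averages out within a cohort.
* $\epsilon_s(v,d) = \max(N(0, \tau^2), 0)$ with $\tau = 0.15$:
  truncated-at-zero additive floor noise, keeping densities valid
  without renormalization.

All randomness derives from `(master_seed, subject_index)` through
per-subject sub-streams, so cohorts are pure functions of their
parameters.  The per-subject streams draw voxel-major with corridor
voxels first, which makes `generate_cohort(region = "corridor")` — a
cropped generation covering only the corridor box — bit-identical to
the corridor voxels of the full volume at roughly a quarter of the
cost; replicate studies of fODF-level statistics use it, tracking uses
full volumes.

**What the phantom does and does not emulate.**  It reproduces the
*statistical* structure of the deep-WM crossing problem: dominant
consistent A–P mass, faint consistent M–L mass, direction-structured
per-subject noise, and tissue geometry for seeding/stopping.  It does
not simulate diffusion-weighted signal, Rician noise, spherical
harmonic fitting, partial-volume or registration error, curved
anatomy, or inter-subject spatial misalignment (grids are aligned by
construction — the situation `"roi_pooled"` σ exists for).  Passing the
phantom chain therefore shows the *mechanism* is implemented correctly
and behaves as designed under its stated noise model, not that the
correction is validated on real brains.

## The recovery experiment

The end-to-end check mirrors the motivating scenario: generate a
default 20-subject cohort, reweight the corridor, track from the medial
seed ROI probabilistically, and compare before/after:

* the corridor's M–L band mass fraction (density at $|\varphi| > 81°$
  over total) increases after reweighting — across 100 independently
  seeded cohorts this held in every replicate during development, and
  the acceptance suite requires ≥ 95/100;
* the fraction of streamlines validly connecting seed to the lateral
  target increases in the overwhelming majority of subjects (paired
  one-sided sign test);
* with the M–L bundle removed ($a_{ML} = 0$), the tracking comparison
  shows no systematic change — boosted isotropic noise cannot sustain a
  coherent 18 mm path, so the correction does not hallucinate the
  pathway it is designed to recover.  We place this specificity null at
  the tracking level deliberately: any correction that damps the
  dominant A–P share necessarily raises every *other* share slightly,
  including the isotropic floor inside the M–L band, so a share-level
  null is unattainable by construction whenever the directional
  signature (decrease at 0°, increase at ±90°) is present.

## Numerical choices and degenerate inputs

* Negative input densities are floored to zero at field construction
  and on load, with a count in the load report (which also records the
  input range, so upstream min–max versus raw conventions stay
  auditable).
* All-zero voxels are degenerate: `fodf_to_pmf()` errors, the tracker
  treats them as terminations (`discarded_degenerate`).
* Sample σ uses ddof = 1 (subjects are a sample), computed by
  vectorized moments and cross-checked against `sd()` loops in tests.
* Median thresholds in the change histogram are strict on both sides.
* The undefined-φ tolerance is $10^{-8}$ relative — pure float
  robustness, there is no physical scale to it.
* Seeds: every stochastic step (phantom, seeding, probabilistic
  sampling) takes an explicit integer seed and is bit-stable given it.

## Problem sizes used by the test suite

The suite runs the oracle-equivalence checks on ≤ 10-subject,
≤ $10^3$-voxel instances with the full 362-direction set; the recovery
experiment on 100 corridor-restricted default cohorts plus full-volume
tracking of one default and one $a_{ML}=0$ cohort (20 subjects each,
288 seeds per subject).  These sizes were chosen so the entire suite
completes on a single CPU in well under half an hour while keeping
every statistic at the default phantom dimensions.

## Known limitations

* The tracker is a reference implementation in R: correct and
  reproducible, but not built for whole-brain human tractograms.
* Voxelwise σ assumes aligned grids; real cohorts need prior spatial
  normalization or `"roi_pooled"` mode.
* The reweighted field's scale is arbitrary (it is a quotient); only
  scale-free consumers (pmfs, fractions, shares) should interpret it.
* TRK export is not implemented; streamlines are written as TCK plus a
  TSV status table.
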