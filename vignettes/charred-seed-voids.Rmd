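---
title: "Quantifying internal voids in charred seeds from micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying internal voids in charred seeds from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charvoid)
```

## The measurement problem

When a soybean is charred under anoxic conditions, its oil coalesces into
droplets that migrate through the heat-modified protein matrix and escape,
leaving behind a population of spheroidal internal voids ("holes") tens to
hundreds of micrometres across. The size spectrum of those holes carries a
compositional signature: oil-rich seeds develop many small holes, while
protein-rich tissue develops fewer, larger ones. Micro-CT makes the holes
measurable non-destructively, which turns charred archaeological seeds into
a record of past selection on seed composition.

charvoid implements the full measurement chain — phantom generation,
tomographic reconstruction, void segmentation, normalized morphometry, and
group statistics — so that the logic linking hole populations to oil and
protein content can be exercised and tested end to end without any
proprietary imaging software or access to archaeological material.

## The phantom generator

No public volumetric dataset accompanies this kind of study, so the
package's synthetic-data generator is a first-class, tested component. It
emulates the established qualitative effects with the simplest monotone
quantitative model:

* **Hole counts.** Per-seed counts in the Small, Medium and Large
  categories are Poisson with log-linear means:
  $\lambda_S = e^{a_0 + a_1 O}$, $\lambda_L = e^{b_0 + b_1 P}$,
  $\lambda_M = e^{c_0 + c_1 (O+P)/2}$, where $O$ and $P$ are oil and
  protein percentages of dry mass. The coefficients
  (`hole_rate_coefficients`: $a_0=5$, $a_1=0.10$, $b_0=1$, $b_1=0.06$,
  $c_0=3$, $c_1=0.08$) were fixed once so that the three reference
  cultivars — P48.7O19.2 (Meng), P42.5O15 (Fu), P33.9O23.6 (Tiefeng) —
  produce the observed orderings (most Small holes for the high-oil
  cultivar, the largest Large-category mean for the high-protein
  cultivar) with per-seed totals of a few thousand holes, matching
  rank-size curves that extend past rank 2500. A caveat of the chosen
  mean-composition form for $\lambda_M$: it gives Fu and Tiefeng nearly
  identical Medium-category rates, so the generator does not encode a
  Tiefeng-above-Fu Medium contrast.
* **Charring temperature.** "About half the number" of Small holes at
  300&nbsp;°C versus 275&nbsp;°C is implemented as an exact factor 0.5,
  which keeps the property testable.
* **Water saturation.** Soaking before charring enlarges the seed
  envelope by a linear factor 1.4 and forces
  $\lambda_S = \lambda_M = 0$, so a saturated seed retains no hole below
  $10^{-5}$ normalized volume. Whether the observed 1.4× enlargement is
  linear or volumetric is not knowable from the source report; linear was
  chosen (the more conservative reading) and is flagged here.
* **Hole sizes.** Each hole's mean radius is log-uniform over the radius
  range implied by its category's normalized-volume decade and the seed's
  analytic envelope volume, intersected with the physically observed
  10–500&nbsp;µm band; a mild triaxial aspect jitter (axis ratios
  0.75–1) is applied at fixed volume so the drawn decade is preserved.
* **Cracks and breaks.** Cracks are thin plates (thickness-to-extent
  ratio ≤ 0.1, at least ~3.6 voxels thick so a tilted sheet voxelizes
  into a 6-connected component); a cotyledon-separation break is a planar
  gap through the seed centre. Both are recorded in the ground truth with
  their own class labels.

Placement is uniform inside the envelope with enough margin that every
ground-truth hole lies strictly inside the seed surface. Voxel-resolvable
voids are kept disjoint by a rejection sampler that uses the ellipsoid
support function along the line between centres — projection separation on
that axis guarantees disjoint voids, and for thin plates the directional
support is far smaller than a bounding sphere, so dense configurations
still pack. Everything is drawn from a single seeded RNG stream: the same
`phantom_spec` always yields bit-identical volumes and ground truth.

The default seed measures 5.1 × 2.5 × 2.4&nbsp;mm (the printed dimensions
of a large-mode archaeological specimen) and is voxelized at 55&nbsp;µm,
spanning roughly 96 voxels along its long axis.

## Resolution: what the tests can and cannot show

A hole in the Small category has normalized volume of order $10^{-7}$ of
the envelope. For such a hole to occupy at least the `n_min = 10` voxels
that the outlier rule requires, the envelope must span at least $10^8$
voxels — a grid of roughly 465³ or finer, which is exactly the regime of
the real scans (3.25&nbsp;µm pixels over a ~16&nbsp;mm³ seed is about
$5\times10^8$ voxels). At the ~96-voxel scale the package uses for its
replicated experiment suites, Small and Medium holes are sub-voxel by
construction: no segmentation algorithm could see them, at any quality.

The test strategy therefore splits cleanly in two:

1. **Group statistics** (cultivar, temperature and saturation contrasts)
   are computed from the generator's ground-truth hole tables, routed
   through the same `normalize_holes()` → `categorize()` →
   `seed_metrics()` → ANOVA/t-test code path as measured data would be.
   This validates the composition model and the statistical machinery at
   the full published population sizes.
2. **Segmentation fidelity** (hole recovery ≥ 95%, volume error ≤ 10%,
   crack contamination < 1%, flood-fill oracle equivalence) is validated
   on reduced phantoms whose voids are voxel-resolvable (mean radii
   35–80&nbsp;µm at 10&nbsp;µm voxels, i.e. 3.5–8 voxel semi-axes, far
   above `n_min`). At that scale the voids sit above the decade bins of
   the small envelope and surface as `above_range` — deliberately so;
   these phantoms test the measurement chain, not the category
   statistics.

Passing tests consequently show that (a) the generator's composition
effects propagate through quantification and statistics exactly as the
published contrasts describe, and (b) the segmentation measures resolvable
voids accurately. They do not show that real charred tissue at real noise
levels segments this cleanly — real envelopes are not perfect ellipsoids,
real holes are not perfect spheroids, and beam hardening, rings and
phase-contrast fringes are all outside the forward model.

## Reconstruction

Raw counts are corrected with the standard flat/dark normalization
$p = -\ln\!\big((I - \bar D)/(\bar F - \bar D)\big)$, with the flats and
darks averaged pixelwise and transmittance clamped at $\varepsilon =
10^{-6}$ before the logarithm so the output is always finite. A mean flat
that nowhere exceeds the mean dark is a data error naming the first
offending pixel.

Reconstruction is slice-by-slice parallel-beam filtered back projection.
The ramp filter is the discrete Ram–Lak kernel assembled in the spatial
domain (which avoids the DC bias of a naïve $|\omega|$ ramp) with optional
Hann apodization for noisy data; sinogram rows are zero-padded to the next
power of two of twice the detector width. The back projector uses linear
detector interpolation and the $\pi/(2N_\theta)$ quadrature weight for
angles covering $[0, \pi)$. On a noiseless uniform-disk phantom the
interior mean reconstructs to within 0.01% of the true attenuation; the
5% acceptance bound leaves room for discretization at other geometries.
Angles must be strictly increasing in $[0, \pi)$; equally-sloped and
cone-beam geometries, ring correction and centre-of-rotation search are
out of scope.

Coordinates are (z, y, x) with 0-based voxel indices; physical positions
are index × voxel size at voxel centres. Volumes store attenuation in
mm⁻¹.

## Segmentation and classification

The seed envelope is obtained by thresholding (Otsu on the 256-bin
intensity histogram by default, or a fixed value), keeping the largest
26-connected material object, closing it with a 3×3×3 box, and filling
every cavity not 6-connected to the grid border. The 26/6 material/void
connectivity pair is the standard complementary choice that avoids
topological paradoxes. The closing seals narrow channel mouths so that a
void opening to the outside remains a detectable component, flagged
`touches_exterior`; because closing is extensive, material plus voids
still partition the envelope exactly (a tested invariant).

The envelope — material *plus* enclosed voids — is the normalization
divisor $V_{seed}$. "Seed volume" could also be read as material only;
envelope was chosen as the natural meaning of a whole bean's volume, and
both numbers are carried on every `seed_mask` so the alternative is one
field away.

Each void component gets principal semi-axes from the eigenvalues of its
voxel-coordinate covariance (×5, the solid-ellipsoid relation), with the
single-voxel 1/12 variance term added per axis — this makes a one-voxel
component isotropic rather than degenerate and supports anisotropic
voxels by scaling each axis by its physical pitch. Classification applies
the exclusion rules in order, all thresholds overridable via
`classifier_rules()`:

| rule | default | meaning |
|---|---|---|
| `n_min` | 10 voxels | below: `outlier` (too small to differentiate) |
| `f_break` | 0.05 | volume above this fraction of the envelope: `break` |
| `tau_break` | 0.3 | exterior-connected and planarity below: `break` |
| `tau_crack` | 0.15 | planarity (c/a) below: `crack` |

Only `hole` components enter quantification; cracks thick enough to evade
`tau_crack` pass as holes and are reported by `crack_contamination()`,
which the validation suite holds below 1%.

## Quantification

Normalized hole volume $v_i = V_i / V_{seed}$ is binned into half-open
decades with inclusive lower edges — Small $[10^{-7}, 10^{-6})$, Medium
$[10^{-6}, 10^{-5})$, Large $[10^{-5}, 10^{-4})$ — the only convention
that makes the three categories exhaustive and disjoint. Values below
$10^{-7}$ map to the outlier exclusion (`below_range`); values at or
above $10^{-4}$ are flagged (`above_range`) rather than silently kept.
Normalized counts are reported in mm⁻³. Rank-size curves sort holes from
large to small with ties broken by component label (stable and
scale-invariant); curves include every retained hole. $L \times W \times
T$ seed-dimension products are rounded to one decimal as conventionally
printed.

## Statistics

Per-seed category counts are compared with one-way ANOVA (`stats::aov`).
The post-hoc family is gated by Levene's test, mean-centred
(`car::leveneTest`), at α = 0.05 — the conventional criterion in the
SPSS-style workflow this mirrors; the homogeneity criterion is not
derivable from the source description, and mean-centred Levene at n = 7
keeps the equal-variance branch about 94% of the time under a true null.
Both post-hoc tables are always computed so either can be inspected:

* **Fisher's LSD** — pairwise t tests on the pooled ANOVA error term.
* **Dunnett's T3** — Welch statistics with Welch–Satterthwaite degrees of
  freedom, referred to the studentized maximum modulus over the
  $k(k-1)/2$ comparisons. The SMM tail for $k$ independent $t_\nu$
  variates has the closed form $1 - (2F_\nu(q) - 1)^k$, exact at any
  (fractional) df, so it is evaluated from `pt()` directly rather than by
  Monte Carlo or table lookup; a seeded Monte-Carlo oracle cross-checks
  it in the tests, and simultaneous confidence intervals use the matching
  SMM critical value.

Two-group temperature comparisons use the two-tailed Student t test
(Welch via a flag). Calibration is tested under seeded nulls: ANOVA
type-I error in [0.04, 0.06] at 2000 replicates, and T3 family-wise error
at or below α plus two Monte-Carlo standard errors under unequal
variances. Categories are tested separately; no cross-category multiplicity
correction is applied, matching the source workflow.

## Problem sizes

The replicated suites run at sizes chosen to exercise the published
designs exactly: 20 suites × 3 cultivars × 7 seeds for the composition
contrast, 100 suites × 2 × 6 seeds for the temperature contrast, 5
saturated seeds, 20 validation phantoms (~110×90×80 voxels each) for
segmentation, 2000-replicate nulls for calibration, and a ~64³
reconstruction round-trip. The whole test suite and the acceptance script
each complete in about a minute on one CPU.

## Known limitations

* The composition → rate coefficients reproduce orderings and ratios,
  not absolute published counts (group means are published only
  graphically).
* The Medium-category rate uses mean composition and cannot express a
  Tiefeng-above-Fu Medium contrast.
* The forward model is pure attenuation: no phase contrast, beam
  hardening, detector PSF or ring artefacts.
* Segmentation assumes a single seed per volume and a thresholdable
  (near-bimodal) intensity distribution; watershed splitting of merged
  holes is out of scope.
* Whether rank curves should include all retained holes or only certain
  categories is not specified in the source workflow; all retained holes
  are included here.
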