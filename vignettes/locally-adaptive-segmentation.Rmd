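---
title: "Locally adaptive fuzzy c-means segmentation of micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally adaptive fuzzy c-means segmentation of micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miaclust)
```

## The problem

Micro-CT scans of bone — and especially of fossil bone — have to be
segmented into material phases (air, bone, invasive matrix) before any
morphometric quantity such as trabecular thickness can be measured. Global
intensity thresholds fail on such data for two reasons: spatially smooth
intensity inhomogeneity (for dense fossils, a center-bright artifact that is
effectively the inverse of beam hardening) moves the same material across
any fixed threshold, and the intensity ranges of fossil bone and
mineralized matrix can overlap globally even where they are locally
distinct.

`miaclust` segments a volume in two stages. A *global* stage clusters the
voxel intensities into a user-chosen number of classes; a *local* stage
then re-runs the clustering inside small overlapping cubes, where
inhomogeneity is negligible, and merges the per-cube results. The number
of classes and the cube size are the only two parameters that must be
chosen, and both can be read off the image itself.

## The model

### Global stage

Voxel intensities $x_k$ (restricted to an optional analysis mask) are first
clustered by K-means into $C$ classes. Because the feature is
one-dimensional, the optimal K-means partition consists of contiguous runs
of the sorted values; `kmeans_init()` finds the exact minimum of the
within-cluster sum of squares by dynamic programming over the intensity
histogram (divide-and-conquer split-point optimization,
$O(C\,n\log n)$ on $n$ distinct values). This removes every source of
randomness and every local optimum from the initialization: a given volume
always yields the same class centers.

The K-means centers seed a fuzzy c-means (FCM) iteration. Each voxel
carries a membership vector $u_{k} = (u_{1k},\dots,u_{Ck})$,
$\sum_c u_{ck} = 1$, updated together with the class centers $v_c$:

$$u_{ck} = \Bigl[\sum_{j=1}^{C}
  \bigl(|x_k - v_c| / |x_k - v_j|\bigr)^{2/(m-1)}\Bigr]^{-1},
\qquad
v_c = \frac{\sum_k u_{ck}^m x_k}{\sum_k u_{ck}^m},$$

with fuzziness exponent $m$. A voxel coinciding exactly with one or more
centers splits its unit membership equally among them. The fuzzy objective
$J = \sum_{c,k} u_{ck}^m (x_k - v_c)^2$ is non-increasing across
iterations (asserted in the test suite on the recorded trace).

### Local refinement

The volume is covered by overlapping cubes of edge $g$ (origins every
$s = \lceil g/2 \rceil$ voxels by default, final origin clamped to the
boundary; every voxel is covered by 1–8 cubes at the default stride). Per
cube:

1. **Class presence.** The global memberships are summed over the cube's
   in-mask voxels, $S_c = \sum_{k \in \text{cube}} u_{ck}$. A class with
   $S_c < \theta \cdot n_\text{cube}$ (default $\theta = 2\%$) is dropped
   from that cube — it has no meaningful support there, and keeping it
   would force the local clustering to hallucinate structure.
2. **Local FCM.** If at least two classes survive, FCM is re-run on the
   cube's intensities, seeded with the surviving global centers and the
   global memberships renormalized over the survivors. A single surviving
   class receives membership 1 throughout the cube. A constant cube, or a
   cube whose local centers collapse (two classes locally
   indistinguishable), keeps the global field: there is no local
   information to refine.
3. **Merging.** Each voxel's final membership vector is the unweighted
   mean over all cubes covering it, renormalized to sum to one. The mean
   is the simplest merge rule consistent with treating each covering cube
   as an equally credible local expert; a distance-weighted variant was
   considered and rejected as an extra parameter without a demonstrated
   benefit.

### Hard assignment and the probability threshold

Voxels are labeled with their highest-membership class (ties to the lowest
index, deterministically), using labels $1..C$ ordered by ascending class
center; label 0 is reserved for background and sub-threshold voxels. An
optional probability threshold excludes voxels whose highest membership
does not *meet or exceed* the threshold; since memberships sum to one,
only the 50 integer percentages 51–100 are distinct thresholds, and 50% is
accepted as an explicit "off" alias (for two classes the maximum of two
probabilities summing to one is always at least ½). Thresholded voxels are
labeled 0 and can be read as the segmentation's margin of error.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `n_classes` | material phases to separate | — | read off the specimen (air/bone, or air/bone/matrix) |
| `grid_size` | cube edge, voxels | — | slightly larger than the widest structure of interest; see below |
| `class_presence_threshold` | minimum fraction of a cube's membership mass for a class to survive locally | 0.02 | small enough to keep any real local phase, large enough to drop absent ones |
| `prob_threshold` | cutoff on the winning membership (51–100%, or off) | off | fine-tuning for abrupt phase boundaries; thickness shrinks monotonically as it rises |
| `fuzziness` | FCM exponent $m$ | 2.0 | the universal FCM default; $m \to 1$ hardens, larger $m$ blurs |
| `tol` | relative center-change convergence tolerance | 1e-5 | intensity-scale-free; tighten to 1e-9 when comparing stages analytically |
| `max_iter` | per-FCM iteration cap | 100 | converges in far fewer on real histograms |
| `stride` | cube origin spacing | $\lceil g/2 \rceil$ | 50% overlap: symmetric coverage, at most 8 cubes per voxel |

`suggest_grid_size()` encodes the grid-size rule: measure the widest
structure of interest (in µm or voxels) and take `round(width) + margin`
voxels (margin 2 by default, floor 3). A 40 µm wire at 7.86 µm/voxel is
about 5 voxels wide, giving a grid size of 7; trabeculae of about 15
voxels give 20 with a margin of 5. A grid much smaller than the structure
makes the local stage search for classes inside the phase of interest and
break it up; a much larger grid degenerates toward the global
segmentation.

## Thickness validation

Segmentation accuracy is validated the way bone morphometry validates it:
by measuring a structure of known thickness. `local_thickness()` implements
the sphere-fitting definition — the thickness at a point is the diameter of
the largest sphere that contains the point and fits inside the structure —
via an exact Euclidean distance transform, a distance ridge (spheres not
contained in any neighbor's sphere), and sphere painting that assigns every
voxel the largest covering diameter. Distances are measured between voxel
centers, so the nearest background center lies half a voxel beyond the
physical interface on each side and diameters are reported as $2r - 1$:
an axis-aligned slab of $n$ voxels (n odd) reads exactly $n$. Space
outside the volume is treated as structure, so open cut faces do not bias
the map. Summary statistics are computed per foreground voxel ("measured
at every point"), not per medial sphere.

## Synthetic phantoms

`make_phantom()` generates ground-truth volumes so that every algorithmic
claim is testable without scan data:

* `plate_coil` — a square-wound coiled plate spanning the volume in z,
  emulating a machined reference coil of rectangular cross-section. The
  spiral path is traced on the voxel grid and dilated by a $t \times t$
  square, so every wall is axis-aligned and exactly $t$ voxels thick; the
  digitized ground truth therefore measures exactly $t$ under
  sphere-fitting, which is what a metrology reference requires. (An
  obliquely digitized wall systematically under-reads by a few tenths of a
  voxel under center-based sphere fitting — an artifact of hard
  digitization, not of the instrument, and the reason the walls are kept
  axis-aligned.)
* `trabecular_lattice` — a connected axis-aligned rod lattice of the given
  rod thickness, a standing proxy for trabecular struts.
* `fossil_like` — a bone-level lattice inside an ellipsoidal body filled
  with brighter invasive matrix (matrix attenuates above bone), cut by
  background-level planar cracks.

Artifacts are applied in a fixed order — multiplicative center-bright
radial ramp $1 + a\,(1 - r/r_\text{max})$ over the structure
($r_\text{max}$ = largest center distance over the structure, so the ramp
spans its full amplitude across the object), near-saturation bright
inclusions at the stated density, additive Gaussian noise, clipping and
rounding to the bit-depth range — using a private RNG stream seeded from
the phantom spec. Identical specs give bit-identical phantoms, and the generator
never touches the caller's RNG state.

What the phantoms deliberately do **not** model: partial-volume boundary
voxels (edges are hard), physics-based projection/reconstruction noise
(noise is i.i.d. Gaussian), ring artifacts, and anatomically realistic
trabecular microarchitecture. Passing the phantom suite therefore shows
that the algorithm recovers known geometry under inhomogeneity, inclusions
and noise; it does not certify behavior on gradual partial-volume edges,
where the probability threshold is the intended fine-tuning instrument.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run the package's own validation
experiments at sizes chosen to keep a desk run in minutes:

* Wire recovery: a 64×256×256 coiled-plate phantom, wall thickness 5
  voxels at 7.86 µm, 10% gradient, noise sd 1500 (16-bit), segmented with
  2 classes and grid size 7. The mean sphere-fitting thickness of the
  brighter class is compared with the known 5 voxels (the acceptance rule
  asks for agreement within 1%, and also within one voxel).
* Threshold monotonicity: thresholds 50–95% in steps of 5 on a
  32×128×128 phantom; mean thickness must be non-increasing. (The
  phantom's hard edges make memberships nearly crisp, so the curve is
  close to flat — unlike partial-volume data where it falls linearly.)
* Locality fixed point: with a volume-spanning cube, no dropped classes
  and a tight tolerance (1e-9), the refined field must reproduce the
  global field to 1e-6 per membership. (At looser tolerances the extra
  refinement pass can legitimately move memberships by more than the
  comparison slack, so this check pins `tol` rather than relying on the
  default.)
* Oracle suites: exact-DP optimality of the 1D K-means on 100 random
  mixtures; sphere-fitting thickness against an exhaustive
  every-center-every-radius oracle on 50 random 12³ blobs; the FCM
  membership update against a direct evaluation of its formula.
* Gradient robustness: a 64×128×128 fossil-like phantom whose 50%
  center-bright ramp exceeds the 33% bone→matrix center gap, so the
  phases' global intensity ranges overlap. Following the fossil recipe
  (median filter kernel 3, background threshold, then clustering of the
  in-mask phases), the Dice overlap of the bone class after local
  refinement must strictly exceed the global-only Dice.

## Numerical choices and degenerate inputs

* Membership updates use the max-stabilized form
  $(d_\text{min}/d_c)^p / \sum_j (d_\text{min}/d_j)^p$, immune to
  overflow for voxels lying close to a center.
* Convergence is declared when the largest center move, divided by the
  intensity spread, drops below `tol` — a scale-free criterion that
  behaves identically for 8- and 16-bit data.
* Two centers closing within $10^{-9}$ of the intensity spread raise a
  collapse error naming the classes at the top level; inside a local cube
  the same event (plus exactly constant cubes) falls back to the global
  field for that cube instead of aborting a whole-volume run.
* Argmax ties label the lowest class index; threshold comparisons are
  inclusive; background-masked voxels carry zero membership and label 0
  but keep their original intensities (the mask is carried separately, so
  preprocessing is non-destructive and inspectable).
* The global FCM runs on the compressed intensity histogram whenever the
  volume has few distinct values (always true for integer CT data); the
  expansion back to voxels is exact, since membership depends only on
  intensity.
* `thickness_sweep()` over the probability threshold segments once and
  re-assigns labels per value: the pipeline is deterministic and the
  membership field does not depend on the threshold, so each row is
  identical to a full run at that value.

## Known limitations

* Intensity is the only clustering feature, as in the underlying method;
  textures or gradients are not used.
* Sphere-fitting thickness on hard-digitized oblique walls carries the
  usual few-tenths-of-a-voxel digitization bias (see above); real scans
  with partial-volume boundaries sit closer to the continuous definition.
* Matrix–air interface rings that share the intensity band of bone are
  segmented as bone, as in the original method; removing them needs a
  connected-component step outside this package's scope.
* Even-width axis-aligned slabs read one voxel thin under the $2r - 1$
  convention (odd widths are exact); this parity artifact is inherent to
  voxel-center sphere fitting.
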