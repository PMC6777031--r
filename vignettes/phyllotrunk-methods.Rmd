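---
title: "Methods: reading cylindrical phyllotaxy out of a trunk scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reading cylindrical phyllotaxy out of a trunk scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllotrunk)
```

## The model

A woody stem lays down its nodes in a spiral during primary growth. On an
idealized cylinder of radius $R$, node $n$ sits at height $z_n = n\,r$
(the *rise* $r$ is the internode distance) and azimuth
$\theta_n = n\,d \bmod 2\pi$ (the *divergence angle* $d$). Dormant buds
keep a radial vascular trace from the pith to the bark through all later
secondary growth, and these traces are bright in tomographic slices, so
the juvenile lattice is recoverable from an adult trunk.

The package's estimation path is:

1. **Pith.** In each slice, a breadth-first flood fill from a seed pixel
   finds the nearest pixel whose intensity lies in the pith range $C$,
   and the centroid of the connected component of in-range pixels around
   it is the pith center. The center of slice $i$ seeds slice $i+1$,
   under the assumption that the pith moves little between slices.
2. **Radius.** Sobel gradient magnitudes are thresholded at a percentile
   (default the 99th) of the whole slice's magnitude distribution; the
   per-slice radius is the median distance from the retained pixels to
   the pith, and the trunk radius is the median over slices with a
   bootstrap standard error.
3. **Unwrapping.** Each slice is resampled to polar coordinates about its
   pith center by nearest-integer lookup,
   $P_i(r,\theta) = Z_i(\mathrm{nint}(x_i + r\cos\theta),\,
   \mathrm{nint}(y_i + r\sin\theta))$, turning radial trace wedges into
   vertical blocks.
4. **Boundary image.** Each polar column is condensed to the mean of its
   intensities inside a foreground range $T$ (tree, not background or
   pith), giving the cylinder-surface image $B(i, \theta)$ whose blobs
   are trace footprints.
5. **Nodes.** $B$ is binarized by Otsu's method; wrap-aware connected
   components become blobs; blob centroids (circular mean in $\theta$)
   become nodes $(z, \theta)$, sorted by height and labeled $0..q-1$.
6. **Phyllotaxy.** Divergence, rise, Adler visibility intervals,
   parastichy families and intersection angles, the conspicuous pair and
   fraction, contact parastichies from a periodic Delaunay
   triangulation, and permutation motifs.

The key modeling assumptions: the trunk is approximately a cylinder (one
radius summarizes it), traces run radially from pith to bark, one blob
corresponds to one node, and the node pattern is a perturbed regular
lattice (so wrapped successive differences estimate $d$).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `C` (pith range) | [0, 0.15] | normalized intensity | pith is the dark hollow center; data-dependent, always configurable |
| `T` (foreground) | [0.2, 1.0] | normalized intensity | excludes background and pith from the radial means |
| `alpha` | 2π/720 (0.5°) | rad | sub-pixel arc at the rim for a few-hundred-pixel slice |
| `s` | 0.5 | px | radial oversampling to stabilize column means |
| Sobel percentile | 99 | — | keeps only the strongest edges: the bark/air rim |
| Otsu bins | 256 | — | the classical gray-level histogram resolution |
| `minArea` | 4 | bins | suppresses speckle without touching real trace footprints |
| `wrap` | TRUE | — | θ = 0 and θ = 2π are the same ray on the cylinder |
| `gapRule` | `as_printed` | — | see below |
| `kMax` | 6 | — | Adler intervals beyond (13, 21) are unresolvable at small q |
| motif `tol` | 0.02 | turns | must stay below d*/2 to avoid aliasing between d* and 2d* |
| bootstrap | n = 1000, seed 0 | — | SE of the median radius |

Intensity ranges are defined on globally (not per-slice) min–max
normalized volumes, because the boundary image compares intensities
across slices.

## Numerical and design choices

**Handedness first.** All wrapped angular steps are taken in the
direction of the genetic spiral (the direction in which the mean
counter-clockwise-wrapped step is below π, ties to CCW), so the reported
$d$ always lands in (0°, 180°] and is comparable to the golden angle
regardless of the specimen's chirality. A consequence worth knowing: in a
heavily permuted sequence each swap adds a full turn's worth to the sum
of wrapped gaps, and enough swaps on a short series can flip the detected
handedness; the motif machinery therefore assumes permutations are sparse
relative to q.

**Divergence averaging.** The mean can be taken over the steps between
nodes 1..q−1 (`as_printed`, the default, matching the formulation with a
$q-2$ denominator that omits the first gap) or over all q−1 steps
(`all_gaps`). On regular lattices both are exact; on real data they
differ by a fraction of the standard error. Both are kept because the
omission of the first gap looks like an off-by-one in the source
formulation; the default favors comparability.

**Adler intervals in exact rationals.** Interval endpoints are ratios of
Fibonacci numbers; membership of $d^*$ is decided by integer cross
multiplication against a rational approximation of $d^*$ at a stated
decimal precision (default 9 digits), so no membership decision ever
hinges on floating-point rounding. The pair sequence is (1, 2, 3, 5, 8,
…); the $k=2$ endpoint needs the preceding term, taken as 1, and the
classical pair (1, 2) at $k=1$ is special-cased to [1/6, 1/2] (divergence
angles between 60° and 180°), its textbook visibility range.

**Cylindrical generator.** Nodes are generated as
$\theta_n = n\,d \bmod 2\pi$ with $d$ in radians. A formulation dividing
the angle by $2\pi$ before wrapping is dimensionally inconsistent (it
would make $\theta$ unitless turns wrapped modulo radians) and is treated
as a typographical slip rather than implemented.

**Intersection angles on the unrolled cylinder.** Parastichy families of
orders m and n are drawn through the observed nodes by linear
interpolation in the plane $(R\,\theta, z)$ — arc length against height,
so that an angle is a geometric angle on the cylinder surface rather than
an artifact of axis units. At each node carrying a segment of both
families, the angle between the local segments comes from the law of
cosines and is folded to the small angle $\min(a, 180° - a)$; azimuth
differences are wrapped to (−π, π] so no segment spans more than half the
circumference. On noiseless lattices this reproduces the closed-form
angle between the lattice vectors $v_k = (R\,\mathrm{wrap}(k d),\, k r)$
to 1e−6 degrees (a tested invariant). Whether a published measurement
used arc-length scaling or raw θ is often unstated; raw-θ scaling would
change the numerical angles but rarely the identity of the conspicuous
pair, since the ordering of |angle − 90°| is preserved under moderate
rescaling.

**Conspicuous fraction.** Candidates are the alternate Fibonacci ratios
1/2, 1/3, 2/5, 3/8, 5/13, …; the scan stops once denominators exceed the
node count (finer fractions cannot be resolved from q nodes), and ties
break toward the smaller index. Conspicuous-pair ties break toward the
smaller pair. Both tie rules exist purely for determinism.

**Otsu.** The threshold maximizes the between-class variance over the 255
interior boundaries of a 256-bin histogram on [0, 1], with class means
computed over bin midpoints; the mask convention is values ≥ threshold.
A constant image has no threshold and is an error, not a silent guess.

**Periodic Delaunay.** The strip is replicated once to each side in x
(= $R\theta$) and triangulated with `deldir`; edges with an endpoint in
the central copy, deduplicated over images and with self-edges dropped,
are the cylinder's contact edges. One replica suffices when the strip is
taller than wide, but that is verified, not assumed: by default the edge
set is recomputed with an extra replica and any disagreement is an
error. Voronoi cells clipped by the bounding window (the open top and
bottom of the specimen) are flagged unbounded and excluded from area
reasoning; the strip is periodic only in θ.

**Permutation motifs.** With system fraction $d^*$, a swap of adjacent
nodes leaves the gap signature $[2d^*, -d^*, 2d^*]$ (mod 1). For two
swaps of adjacent disjoint pairs, deriving the gap sequence from the
permuted labels gives the five-gap signature $[2d^*, -d^*, 3d^*, -d^*,
2d^*]$; the four-gap shorthand $[2d^*, -d^*, -3d^*, 2d^*]$ is common in
the literature for the same event, even though no permutation of
consecutive labels has consecutive differences (2, −1, −3, 2) — such a
sequence would revisit a label. The detector therefore recognizes both
forms as `DOUBLE_TWO_PERM` and reports which multiplier sequence matched.
Longer motifs are matched first and shorter matches inside an already
matched window are suppressed. Each element is compared modulo 1 within
`tol`; note that for $d^*$ near 2/5 the values $2d^*$ and $-3d^*$ are
close modulo 1 (they coincide exactly at 2/5), which is why the
four-element shorthand alone would misfire near Fibonacci fractions and
the full-window match is required.

**Degenerate inputs.** Flood fill with no reachable in-range pixel,
radius estimation retaining no pixels, a constant boundary image,
triangulating fewer than 4 or collinear nodes, and empty rescue ROIs are
all hard errors naming the slice or stage. Empty node files are a warning
plus an empty set; θ recorded as exactly 2π is wrapped to 0 with a
warning. Nearest-integer resampling rounds half away from zero.

## What the phantom emulates — and what it does not

`generateTrunkVolume()` renders: a circular trunk cross-section with a
sinusoidal ring texture confined to the foreground range (so rings never
masquerade as traces at default thresholds), a dark pith disk that may
drift linearly across slices, bright radial wedges spanning pith to bark
(configurable partial extent) at the lattice node positions with a given
angular width and height in slices, and clipped additive Gaussian noise.
Defaults describe a desk-scale specimen geometrically similar to a young
cherry trunk: radius 2.5 cm (50 px at 0.05 cm pitch), 20 nodes, d = 143°,
rise 1.5 cm, traces 4° wide and 3 slices (0.75 cm) tall, noise σ = 0.02.
The volume is a deterministic function of the spec, including its seed.

It does **not** emulate: non-circular cross-sections, bark texture,
branch junctions (as opposed to bud traces), intensity inhomogeneity or
bias fields, partial-volume blur between slices, ring eccentricity, or
scanner-specific noise statistics. Passing recovery tests on phantoms
therefore demonstrates the pipeline's internal consistency — that the
geometry is inverted correctly and thresholds behave — not robustness to
every artifact of real scans, where the intensity ranges C and T, the
pith seed and occasional blob rescues remain data-dependent,
operator-supplied choices.

## Problem sizes used by the tests

The module tests run phantoms of 96–128 px slices with 12–20 nodes
(about 80–130 slices), chosen so the whole suite exercises every stage,
including four full pipeline passes for the noise-monotonicity check, in
well under a minute of compute. The acceptance script runs the default
20-node, 128-px phantom once. Larger, scan-sized volumes (hundreds of
250-px slices) run through the identical code path; only wall-clock time
grows.

## Known limitations

- One global radius is used to place nodes on the cylinder; strong taper
  biases arc-length-dependent quantities (intersection angles), though
  not the divergence or rise estimates.
- The per-slice radius assumes in-plane isotropy: only the pixel pitch
  enters, which is the natural reading when slices are axial.
- Blob rescue is manual by design (an operator names the ROI); there is
  no automatic second-pass detection.
- Non-Fibonacci (Lucas, bijugate) systems are outside the visibility
  machinery's default scan, although the interval construction
  generalizes.
- DICOM series must be converted to TIFF/PNG stacks upstream; the reader
  ingests TIFF/PNG with user-supplied voxel geometry.
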