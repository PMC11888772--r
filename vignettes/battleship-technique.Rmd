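---
title: "Scoring talar-dome distance maps with the Battleship technique"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring talar-dome distance maps with the Battleship technique}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstmap)
```

## The problem and the model

Weight-bearing CT of the ankle yields, after segmentation, triangulated
surfaces of the talar dome and the tibial plafond. The *distance map* of
the joint assigns to every point of the dome the gap to the opposing
plafond; regions of close contact mark where load concentrates, and their
position over the dome shifts with hindfoot malalignment (varus feet load
medially, valgus feet laterally).

The Battleship technique (BST) condenses that map into a single point.
The articular surface is projected into the axial plane, its bounding
rectangle is split into a 4 × 4 grid of equal squares (hence the name),
and each square `i` receives a distance-mapping coefficient

$$DMC_i = 1 - \bar d_i,$$

one minus its mean intraarticular distance in millimetres. Squares that
are subchondral cyst holes count their cyst samples as zero distance, so
a fully cystic square attains the maximum $DMC = 1$; extra-articular
osteophytes are excluded before anything is computed. Each square's
weighted sums multiply its DMC by the normalized coordinates
$(c_{x,i}, c_{y,i})$ of its centre relative to the grid axes, and the
totals divide by the fixed number of squares:

$$TWS_x = \frac{1}{16}\sum_{i=1}^{16} DMC_i\, c_{x,i}, \qquad
  TWS_y = \frac{1}{16}\sum_{i=1}^{16} DMC_i\, c_{y,i}.$$

The point $(TWS_x, TWS_y)$ — the distance-map weighted sum (DMWS) — is
the centroid of closeness over the dome. With +x lateral and +y
anterior, $TWS_x < 0$ (a medially weighted contact, the AM/PM quadrants)
classifies the coronal pattern as varus, $TWS_x > 0$ as valgus;
$TWS_y > 0$ as anterior, $TWS_y < 0$ as posterior; an exact zero is
neutral.

### Coordinate conventions

The grid coordinates are a deliberate design choice: the bounding
rectangle is mapped to $[-0.5, 0.5]^2$, so square centres sit at
$\pm 0.125$ and $\pm 0.375$ regardless of the physical size of the
dome. This makes the TWS dimensionless and comparable across feet; the
price is that a TWS value is not a millimetre offset. Two useful
identities follow, with $\sum_i c_{x,i} = 0$ and
$\sum_i c_{x,i}^2 = 1.25$: a uniform distance field gives exactly
$(0, 0)$, and a noiseless linear field
$d = d_0 + g_x c_x + g_y c_y$ gives

$$TWS_x = -\frac{1.25}{16}\, g_x = -0.078125\, g_x$$

(and likewise for y). `tws_gain()` exposes this constant; it is the
closed-form oracle against which the whole pipeline is tested, and it
turns a measured TWS back into an interpretable gradient in mm per dome
width, $\hat g_x = -TWS_x / 0.078125$.

All scoring happens in a right-foot anatomical frame: the axial
projection mirrors left feet so that +x is always lateral. Mesh-free
grid tables use anatomical column order (medial to lateral) for both
sides, so the same table means the same anatomy whichever foot it came
from; tables recorded in an unmirrored image frame can be declared as
such (`columns = "image"`), in which case left-foot columns are reversed
on input.

## Tunable parameters

* `zero_tol` (default 0) and `digits` (default 3): the TWS values are
  rounded to `digits` decimals before classification and compared to a
  neutral band of half-width `zero_tol`. The clinical rule is exact
  equality to zero; rounding first makes that rule meaningful for
  floating-point values while keeping the default behaviour faithful.
* `axis` / `ap_direction` (defaults world z and +y): the axial
  projection frame. Whether the grid rectangle should align with the
  scanner or with an anatomical talar axis is genuinely open; the
  package therefore takes the direction as an input rather than
  guessing, and the synthetic generator emits meshes in the default
  frame.
* Distance sampling: distances are evaluated at the talar vertices
  (optionally midpoint-subdivided via `subdivide`), each as the exact
  nearest-point-on-triangle distance to the plafond mesh, computed in
  compiled code. A vertex-to-nearest-vertex shortcut would bias
  distances upward on coarse meshes; the nearest-point contract is
  transparent and discretization-robust.

## Statistical toolkit

Reliability uses the single-measure two-way random-effects ICC with
absolute agreement, with the F-based 95% confidence interval, and the
conventional bands (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤
excellent ≤ 1). The printed bands overlap at their endpoints; this
package resolves each endpoint into the higher band, a deterministic
choice. Group comparisons gate on per-group Shapiro–Wilk normality at
0.05: both normal routes to the (Welch) independent-samples t-test with
mean ± SD summaries, otherwise the Mann–Whitney U test with median
[IQR]; correlations gate per variable between Pearson and Spearman and
are reported significant at the stringent 0.001 level. Groups smaller
than 3 cannot be normality-tested and fall back to the rank test with a
warning; groups smaller than 2 are skipped per comparison.

The a-priori sample size uses the Walter-type approximation
$n = 1 + 2k(z_{1-\alpha}+z_{1-\beta})^2 / [(k-1)\ln^2(C_1/C_0)]$ with
$C(\rho) = 1 + k\rho/(1-\rho)$. The null ICC is not part of the usual
clinical statement of such designs; the package defaults to
$\rho_0 = 0$ with a one-sided $\alpha$, the minimal assumption under
which the standard design (k = 3, $\alpha$ = 0.05, power 0.90, target
ICC 0.50) yields the familiar minimum of 15 participants, inflated to
20 by the customary 30% dropout allowance. Both are exposed as
parameters.

## What the synthetic generator emulates

No clinical scans ship with the package; every pipeline stage is instead
exercised on synthetic joints with known ground truth.

* **Field model.** A tilted plafond over the dome is modelled to first
  order as a linear distance field: baseline `d0` (default 0.5 mm, a
  typical joint-space half-width) plus coronal/sagittal gradients
  `gx`, `gy` in mm per normalized unit, additive Gaussian per-square
  noise, and optional fully cystic squares. The linearity is what buys
  the closed-form TWS oracle.
* **Meshes.** `generate_joint_meshes()` realizes the same field as a
  planar dome patch (default 30 × 40 mm) against an offset plafond
  patch oversized by a 2 mm margin, so edge vertices still see interior
  target triangles. At 64 vertices per side the discretized TWS sits
  within about 2% of the closed form (the per-column sample means of a
  finite lattice differ slightly from the square centres).
* **Cohorts.** Each synthetic patient draws `(gx, gy)` from normal
  distributions (defaults n = 40, means −0.08/−0.18, SD 0.25, biasing
  toward valgus and anterior patterns as seen in ankle-OA series); the
  true TWS follows from the closed form. Two raters × two readings add
  Gaussian noise of SD 0.006 on the TWS scale — about a third of the
  between-patient spread of ≈0.02, which is the regime that produces
  ICCs near 0.9 ("excellent" agreement). Alignment angles are linear in
  the true TWS plus noise; the default directions make valgus cohorts
  show higher tibiotalar-surface, hindfoot-alignment, talocalcaneal and
  talar-tilt angles and slightly lower alpha angles, and posterior
  cohorts higher beta angles and tibiotalar ratios. These group-level
  directions are internally consistent, whereas published
  group-difference signs and correlation signs for talar tilt and the
  beta angle cannot both hold under one convention; the couplings are
  therefore user-overridable and the sign convention of the angle
  inputs is treated as a property of the data source, not resolved by
  the package.

Passing tests on these joints demonstrates the *algorithmic* chain —
distance engine, projection, grid bookkeeping, weighted sums,
statistics — not biofidelity: real talar domes are curved, their
distance fields are not linear, osteophytes have geometry rather than
labels, and raters disagree in more structured ways than white noise.

## Numerical choices

* Sample-to-square assignment is half-open with the last row/column
  closed, so every sample lands in exactly one square and rectangle-edge
  samples are kept.
* Empty squares contribute zero weighted sum but the divisor stays 16
  ("the total number of squares" is a fixed total); they are flagged,
  never fatal.
* Squares remain equal subdivisions of the bounding rectangle even when
  a user-supplied anatomical centre is off the rectangle midpoint; the
  centre then only decides quadrant labels (a square belongs to the
  quadrant containing its own centre).
* A partially cystic square interpolates: cyst samples enter the mean
  as 0 mm, so DMC rises continuously to 1 as the cystic fraction grows.
* Degenerate inputs fail loudly with typed validation errors (zero-area
  rectangles, meshes without faces or articular vertices, incomplete
  rating designs naming the missing cells, constant tables for the ICC).
* Perfect-agreement ICC tables make the F-interval degenerate; the
  interval collapses onto the estimate rather than returning NaN.

## Problem sizes

The shipped tests run the mesh pipeline at resolutions 16–64 (the
closed-form recovery at 64 is the most expensive single check), the
grid-level property tests over 1000 random tables, the ICC oracle over
200 random 5 × 3 tables, gradient recovery over 500 noisy replicates,
and the type-I calibration of the gated comparison over 2000 null
replicates — sizes at which the Monte-Carlo error of each check is well
below its assertion tolerance. All simulations are seeded.

## Known limitations

* The distance contract (per-vertex nearest point on the opposing
  surface, talus to tibia) is a declared definition; proprietary
  distance-mapping tools may measure along normals or symmetrize, and
  their values need not agree square by square.
* The dome model is planar; strongly curved or incongruent joints make
  the axial projection compress peripheral squares, which the normalized
  coordinates do not undo.
* Cyst and osteophyte identification is an input (vertex labels or
  flags), not a segmentation capability.
* The brute-force distance kernel is quadratic in mesh size; it is
  comfortable to ~10^4 × 10^4 vertex/triangle pairs but a spatial index
  would be needed for full-resolution clinical segmentations.
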