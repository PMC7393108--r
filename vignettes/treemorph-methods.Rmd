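---
title: "Methods: tree morphometrics and allometry from laser-scanned point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree morphometrics and allometry from laser-scanned point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemorph)
```

## The problem

Dynamic global vegetation models (DGVMs) in the LPJ family grow trees
through a fixed allometric module: height and canopy area are both slaved
to stem diameter through

\[
\mathrm{Height} = 40\,\mathrm{DBH}^{0.5}, \qquad
\mathrm{CA} = 100\,\mathrm{DBH}^{1.6},
\]

with diameter in meters.  Eliminating DBH couples crown size rigidly to
height, \(\mathrm{CA} = k\,\mathrm{Height}^{p}\) with \(p = 1.6/0.5 =
3.2\) and \(k = 100 \cdot 40^{-3.2} \approx 7.47\times10^{-4}\)
(`combine_theoretical()`).  In semi-arid open woodlands, however, trees
are short but wide-crowned: the observed height–crown relation forms a
broad envelope, and the rigid DGVM curve tracks only its lower (5%
quantile) edge.  Quantifying that envelope requires (i) extracting
morphological traits from terrestrial-laser-scanning (TLS) point clouds
of single trees, (ii) fitting power-law *quantile* curves rather than
mean regressions, and (iii) relating plot-mean traits to environment.
This package implements all three stages plus a synthetic-forest
generator with analytic ground truth, so every estimator can be validated
end to end without field data.

## Synthetic forest generator

`make_tree()` builds a stylized broadleaf tree: each stem is a vertical
cylinder **surface** (mimicking laser returns from bark, with full 360°
coverage as from a multi-station scan) sampled on a regular grid from the
ground to the crown base, and the crown is an ellipsoid with semi-axes
\((r_x, r_y, r_z)\) filled with uniformly distributed "leaf" points.  The
analytic ground truth follows from the parameters: true canopy area
\(\pi r_x r_y\), true crown base, true TDR from the stem inventory, crown
LAI \(= u \cdot \tfrac{4}{3} r_z\) for leaf area density \(u\) (mean
vertical chord of the ellipsoid).

Choices that matter:

* **Multi-stem placement.** Stems sit on a circle wide enough that
  adjacent stem surfaces clear the 0.1 m single-linkage threshold used to
  split breast-height slices into stems (with a 0.12 m margin).  Placing
  them at the bare minimum (circle radius = sum of radii) can leave two
  thin stems separated by less than the linkage distance, which merges
  them into one component and makes the per-stem circle fit ill-posed.
* **Optical consistency.** The ray-casting LAI estimator intercepts a ray
  when it passes within `r_beam` of a point.  The generator reports the
  `beam_radius` at which the discrete point cloud reproduces the optical
  cross-section density \(G\,u\) of a Poisson leaf medium with spherical
  leaf-angle distribution (\(G = 0.5\)); using it makes gap fractions of
  the synthetic crown match the analytic Beer–Lambert attenuation.
* **Noise.** Gaussian ranging jitter is available (`jitter_sd`, typical
  TLS value 0.005 m) but defaults to off so exactness tests are exact.
* **Seeds** are explicit arguments everywhere; the global RNG state is
  saved and restored, so identical seeds give bit-identical clouds.

`make_envelope_table()` draws \((x, y)\) pairs whose conditional 5% and
95% quantiles are *exactly* two prescribed power laws: a latent uniform
\(U\) interpolates \((\log a, b)\) linearly between the lower curve at
\(U = 0.05\) and the upper at \(U = 0.95\).  This requires \(y\) to be
monotone in \(U\) across the whole \(x\)-range, which is validated at the
range endpoints (the log-derivative is linear in \(\log x\)).
`make_plot_table()` draws multivariate Gaussian plot records over the 12
trait and 13 environment columns with any valid correlation matrix;
`default_effect_matrix()` encodes a water-availability gradient
(precipitation-linked variables raise height, diameter and leaf size;
radiation-linked variables raise trunk-dominance ratio and leaf tissue
density), projected to the nearest positive semi-definite correlation
matrix.

What the generator does **not** emulate: occlusion and single-side
shadowing, beam divergence and footprint growth, intensity, wind-blurred
returns, understorey, and non-ellipsoidal crown shapes.  Passing the
recovery suite therefore demonstrates correctness of the geometry and
statistics, not robustness to every field artifact.

## Trait extraction

* **Height** is simply `max(z) - min(z)` of the ground-normalized cloud.
* **DBH** takes the 1.3 ± 0.05 m slice, splits it into stems by
  single-linkage components at 0.1 m, and fits a circle per stem with the
  **Taubin** algebraic fit (solved through the SVD in centered
  coordinates).  The Taubin fit is exact on noise-free circles and agrees
  with the iterative geometric (orthogonal-distance) fit to better than
  \(10^{-3}\) relative radius at the noise levels of stem slices
  (\(\sigma/r \le 0.05\)); unlike the Kåsa fit it is nearly unbiased on
  partial arcs.  Slice components with fewer than 3 points are discarded
  as stray returns.  The reported DBH is the largest stem's diameter; the
  full per-stem list feeds the trunk dominance ratio.
* **TDR** \(= \mathrm{num} \times \Sigma d_i / d_{\max}\) over stem
  diameters at 1 m: 1 for a single trunk, \(n^2\) for \(n\) equal stems.
* **Crown base** uses the convex-hull area profile \(A(z)\) over 0.25 m
  layers with a *hysteresis* rule: detect the crown at the lowest layer
  with \(A \ge 0.15\,A_{\max}\) persisting for three consecutive layers,
  then walk down while layers retain at least \(0.02\,A_{\max}\) and sit
  clearly above the trunk cross-section baseline.  A single 0.15
  threshold alone localizes the base with a systematic offset
  \(\approx r_z(1 - \sqrt{0.85})\), which exceeds one layer for crowns
  with \(r_z \gtrsim 3\) m; the low second threshold removes that bias
  while the high threshold still rejects isolated branch stubs.  Profiles
  that never qualify, or never expand beyond the trunk, return 0 with a
  warning flag (shrub-like form).
* **Canopy area** is the maximum convex-hull area over 0.5 m canopy
  layers.  The hull is a Graham scan (polar sort around the lowest point,
  ties broken by distance, collinear vertices dropped); the area is the
  shoelace formula.  The hull of \(n\) uniform points inscribed in a
  smooth convex section underestimates its area at rate
  \(O(n^{-2/3})\), which is why the recovery study samples crowns densely
  (~12000 leaf points keeps the deficit under 5%).
* **LAI** casts a regular angular ray grid from the scanner position; a
  ray is intercepted within `r_beam` of any canopy point.  Per zenith bin
  \(\theta\), the gap fraction inverts through Beer–Lambert,
  \(L_e = -\cos\theta\,\ln P(\theta)/G\) with \(G = 0.5\), corrected by
  the Lang–Xiang clumping index \(\Omega = \ln \bar P / \overline{\ln
  P}\) over azimuth sectors, and averaged over bins.  Saturated bins
  (\(P = 0\)) are excluded with a warning; if every bin saturates the
  estimate is refused.  Saturation is a genuine validity limit of
  gap-fraction inversion, not an implementation detail: once the central
  optical depth \(G\,u\,2r_z\) passes roughly 2.2 the gap probability
  drops below \(e^{-2.2}\) and no finite ray count estimates \(\ln P\)
  stably, so the validation study draws leaf densities inside that
  regime (crown LAI roughly 1–2.5, typical of semi-arid oaks) and tests
  the saturated branch separately.
* **Percentage cover** rasterizes all plot clouds onto a 0.5 m grid and
  counts cells holding a return at or above 2 m.

All geometric traits are invariant to rotation about the vertical axis
and to horizontal translation; the test suite asserts this directly.

## Leaf traits

`sla()` and `ltd()` are the defining ratios (SLA = LA/dry weight, LTD =
dry weight/(LA × thickness)); thickness is stored in cm so LTD is in
g/cm³, and the identity \(\mathrm{SLA}\times\mathrm{LTD}\times t = 1\)
holds for any consistent record.  Leaf area from a binary scan mask is
the hole-filled foreground pixel count times the squared resolution.
Main-vein length is a declared **surrogate**: the mask is thinned to its
morphological skeleton (Zhang–Suen) and the longest geodesic through the
8-connected skeleton graph is measured with the two-sweep farthest-point
method (diagonal steps count \(\sqrt 2\)).  For elongated leaves the
skeleton follows the midrib and the surrogate tracks the vein well; for
near-circular masks the skeleton degenerates toward the center and the
geodesic shrinks accordingly — a known limitation of any
skeleton-based length, which is why round-leaf vein lengths should come
from the measurement table rather than the mask.

## Allometric envelopes

`fit_power_quantile()` minimizes the pinball loss
\(\sum \rho_\tau(y_i - a x_i^b)\).  The key numerical choice: for fixed
exponent \(b\) the optimal coefficient has an **exact** solution — with
\(z_i = x_i^b\) and ratios \(t_i = y_i/z_i\), the inner minimizer is the
\(\tau\)-quantile of the \(t_i\) weighted by \(z_i\), found by one sort.
This avoids iteratively-reweighted schemes that become unstable at
\(\tau = 0.05\) or \(0.95\) where few points sit on one side of the
curve.  The exponent is then a one-dimensional search: an 80-point grid
on \([0.05, 8]\) (covering all allometric exponents of interest with
margin) refined by golden-section to \(10^{-7}\).  The fit is audited in
the tests by a local-optimality sweep (±1% perturbations of \(a\) and
\(b\) never reduce the loss) and by the binomial coverage property (the
fraction of points under the curve is within sampling error of
\(\tau\)).  Exact scale equivariance holds: scaling \(y\) by \(c\)
scales \(a\) by \(c\) and leaves \(b\) unchanged.

`fit_proportional()` is the through-origin least-squares line
\(y = b_0 x\) with \(b_0 = \Sigma xy / \Sigma x^2\) and a t-test on
\(n-1\) degrees of freedom.  `compare_envelopes()` evaluates a fitted and
a theoretical curve on a grid and locates their crossing by bisection on
the log-difference; because the fitted lower-envelope exponent (≈4.6)
exceeds the theoretical 3.2, the gap between the two curves grows
monotonically above the crossing.

## Plot-level statistics

Pearson correlations use the textbook t statistic on \(n-2\) df with
two-sided p-values and significance stars at 0.1/0.05/0.01 (no
multiple-testing correction — the matrix reports raw stars, and the null
calibration test confirms the ~5% false-positive rate).  Partial
correlation is the residual method: correlate the residuals of both
variables after OLS on the controls, on \(n - 2 - k\) df; with no
controls it reduces to plain Pearson exactly, and it equals the
inverse-correlation-matrix formula to machine precision.  Variables
explained exactly by the controls get partial r = 0 by definition rather
than numerical noise.

The trait PCA standardizes columns and eigendecomposes the correlation
matrix — the traits mix units (m, m², g/cm³, ratios), so the covariance
alternative would let canopy area dominate.  Two display conventions are
applied: leaf tissue density and trunk dominance ratio are negated
before the analysis (they vary opposite to the other hydraulic-axis
traits), and each axis's sign is fixed so its largest-magnitude loading
is positive.  Neither affects explained-variance fractions, which always
sum to one over the 12 axes.

Trait clustering represents each trait by its standardized profile
across plots and agglomerates by centroid linkage on squared Euclidean
distances (`stats::hclust`, validated against a direct \(O(n^3)\)
re-computation oracle).  Centroid linkage can produce height inversions;
they are legitimate and flagged on the result rather than hidden.

## Problem sizes and determinism

The validation suite runs, per fixed seed: a 50-tree noiseless recovery
study (12000 leaf points per tree; height within 1%, DBH within 1%,
canopy area within 5%, crown base within one 0.25 m layer, TDR exact,
LAI within 15% of the analytic Poisson-medium value on the same ray
grid), envelope recovery on 20 samples of n = 2000 generated from the
5%/95% curve pair of the semi-arid oak study (median exponent error
well under 15%), and the statistics oracle suite at \(10^{-12}\)
tolerances.  These sizes were chosen so hull convergence, ray-count
noise and quantile sampling error sit comfortably inside each stated
tolerance; all randomness flows through explicit seed arguments, so
every number is reproducible.

## Known limitations

* The crown-base and percent-cover algorithms are declared re-specifications:
  field practice ranges from manual digitization to voxel methods, and
  no single convention is canonical.
* LAI assumes a spherical leaf-angle distribution (\(G = 0.5\)) and the
  Lang–Xiang clumping estimator; other G-functions or clumping models
  change absolute values by tens of percent in heterogeneous crowns.
* The quantile-envelope fit reports no confidence intervals; exponent
  uncertainty at n in the low hundreds is substantial, which is exactly
  why the recovery study quotes a 15% band.
* Individual-tree field data are not bundled; plot-level analyses run on
  synthetic tables with known correlation structure, so conclusions
  about real trait–environment relations require the user's own data.
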