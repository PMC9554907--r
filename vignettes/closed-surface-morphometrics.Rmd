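---
title: "Closed-surface grid fitting and morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-surface grid fitting and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesigrid)
```

## The problem

Vesicles, micelles and pore walls are *closed* interfaces: their shape is
a radial graph $r(\theta, \varphi)$ about an interior center, not a height
field $z(x, y)$. Flat-bilayer tools (xy-grid height maps, planar Voronoi
areas) mis-measure areas and thicknesses on such topologies because the
metric of the surface is curvature-dependent. `vesigrid` fits a smooth
closed surface to the atoms of one interface and derives every
morphometric quantity from that surface, so curvature is accounted for by
construction.

## Surface model and fitting

The atoms of one interface (e.g. the phosphate atoms of the outer leaflet,
selected by an index group) are centered on their geometric mean $C_0$ and
expressed in spherical coordinates $(r_s, \theta_s, \varphi_s)$, with
$\theta \in [0, 2\pi)$ the azimuth and $\varphi \in [0, \pi]$ the
colatitude. Node directions form an equal-angle lattice with spacing
$\Delta\theta = \Delta\varphi = 2\pi/\mathrm{bin}$; the node count is
$(\mathrm{bin}+1)(\mathrm{bin}/2+1)$, with a duplicated seam column at
$\theta = 2\pi$ and single-valued poles enforced exactly.

Each node radius is the Gaussian-weighted mean of atomic radii with the
weight a Gaussian of the *geodesic* distance
$d = r_s \, \Delta\Phi$, where $\Delta\Phi$ is the central angle between
node and atom directions (spherical law of cosines, clamped before `acos`
for stability). Only atoms with $d \le r_c$ contribute, with
$r_c = 3 \cdot 2\pi R_a / \sqrt{n_s}$ — three average circumferences over
the square root of the atom count — which keeps the cost per node bounded
while guaranteeing, at realistic densities, dozens of atoms per
neighbourhood.

Two numerical choices matter here:

* **Underflow-safe weights.** The kernel width $\alpha$ can be orders of
  magnitude smaller than inter-atom distances, making every raw weight
  underflow to zero. Weights are therefore computed as
  $\exp\!\big(-(d^2 - d^2_{\min})/2\alpha^2\big)$ per node; the shift
  cancels in the weighted mean and the nearest atom always carries weight
  1, so the fit degrades gracefully toward nearest-neighbour
  interpolation instead of producing NaNs.
* **Empty neighbourhoods.** A node whose cutoff ball contains no atom
  falls back to an unbounded cutoff (all atoms) with a warning —
  continuity of the surface is preferred over dropping nodes.

### The width power law

The kernel width follows the surface atomic density,
$\alpha = \beta\,\sigma^{-\gamma}$ with
$\sigma = n_s / 4\pi R_a^2$ (atoms/nm²): denser interfaces are fitted with
narrower kernels. The defaults $\beta = 0.0382$, $\gamma = 0.9968$ are the
published closed-surface calibration. `calibrate_alpha()` re-derives
$(\beta, \gamma)$ for any synthetic family: per density it minimizes the
RMSD *against the analytic test surface* over $\log\alpha$ (bounded
search via `stats::optimize`, bounds $[10^{-3}, 10 R_a]$ nm, tolerance
$10^{-4}$ nm), then fits the power law on the log–log table. Minimizing
the residual against the atoms themselves instead is degenerate on
noiseless clouds — smaller $\alpha$ always wins — which is why the
test-surface objective is the default whenever the generator supplies the
analytic radius function, and why perfect-sphere families (where every
weighted mean of a constant is exact) are flagged degenerate rather than
fitted. Averaging the objective over a few replicate clouds per density
(`n_rep = 3`) stabilizes the per-$\sigma$ optimum. On our sinusoidal
family the calibration yields $\gamma \approx 0.3$ with log–log
$R^2 > 0.9$; the exponent is family-dependent, and the published value
belongs to the original (unpublished) test-surface set — the package
treats $(\beta, \gamma)$ as data, not constants.

The grid resolution, if not given, is chosen from the density as
$\mathrm{bin} = \max(12, \sqrt{4\pi R_a^2 \sigma})$ rounded up to even, so
grid spacing tracks the inter-atom spacing.

## Morphometrics

**Triangulation.** Each grid cell is split into two flat triangles,
`{G(i,j), G(i+1,j), G(i,j+1)}` and `{G(i+1,j+1), G(i+1,j), G(i,j+1)}`
(the second wound as `{G(i,j+1), G(i+1,j), G(i+1,j+1)}` internally so all
normals are consistent; the whole set is flipped outward if the signed
fan volume is negative). Cells adjacent to a pole contribute one
zero-area triangle each — these are permitted and excluded from
angle statistics.

**Area** is the sum of Heron triangle areas. **Volume** sums pyramid
volumes $\tfrac13 A_{tp}\, \bar r_{tp} \cos\theta_{tp}$ about $C_0$.
**Sphericity** $\Psi_g = \pi^{1/3}(6V_g)^{2/3}/A_g \le 1$ with equality
for a sphere. Both area and volume converge quadratically in
$1/\mathrm{bin}$ (verified on spheres); at bin = 60 the sphere area is
low by ~0.23%, at bin = 24 by ~1.4% — per-frame CLI analyses at moderate
bins trade this bias for speed, and the bias cancels in ratios such as
$A_L$ trends.

**Deflection angle.** $\theta_{tp}$ is the angle between the surface
normal and the radial direction. The normal is taken from the
*differentiable fitted surface*: for a radial graph the outward normal
direction is
$\hat r - (\partial_\varphi r / r)\hat\varphi - (\partial_\theta r / (r
\sin\varphi))\hat\theta$, with the derivatives from one-sided differences
of node radii across each triangle. On a constant-radius grid both
derivatives vanish identically, so a perfect sphere gives
$\theta_{tp} \equiv 0$ and a curvature order parameter of exactly 1.0 —
a flat-facet normal would instead be biased by half the grid spacing and
could never reach the spherical limit. The flat facet normal is still
computed (orientation checks, divergence-theorem cross-validation).

**Curvature order parameter.** $S_C = \langle P_2(\cos\theta)\rangle$,
area-weighted over triangles (unweighted averaging available); range
$[-0.5, 1]$, decreasing with eccentricity across an ellipsoid family.

**Inertia and roundness.** The inertia tensor of the surface places each
triangle's area as mass at its centroid — a uniform *surface* density.
(Unit node masses are available as an option, but an equal-angle lattice
over-weights the poles: a sphere would then report $I_1/I_3 = 2/3$, which
is a property of the node layout, not of the shape.) The three roundness
indices are: (1) circumference of the equal-area ideal sphere over the
mean perimeter of the three cross-sections through $C_0$ normal to the
principal axes; (2) $\min r_g / \max r_g$; (3) $I_1/I_3$. Cross-sections
in method 1 are traced at the grid's own angular resolution so the
perimeter's polygonal deficit matches the area's faceting deficit —
traced much finer, a perfect sphere would sit visibly below 1. Note that
method 1 can slightly exceed 1 for elongated bodies (the mean
cross-section perimeter can fall below the equal-area circumference);
methods 2 and 3 are bounded by 1.

## Thickness, shells and density profiles

Two leaflet grids fitted about a *common* center (the outer leaflet's, so
radial differences are well defined) give the per-node thickness
$D_{HH}(i,j) = r_{up} - r_{down}$, reported either as a spatial mean per
frame or as a per-node temporal mean over frames. The reference
(mid-) surface averages the two radii node-wise; scaled copies
$k \cdot r_{ref}$ bound shape-conformal shells. Because scaling multiplies
every radius, shell volumes obey $V(k) = k^3 V_{ref}$ *exactly* on the
grid, and the shell-volume table uses this identity. Density profiles
assign each particle the coordinate $k = r / r_{ref}(\theta, \varphi)$
(reference radius bilinearly interpolated at the particle's direction,
seam-aware), bin uniformly in $k$, and divide counts by shell volumes;
$k = 1$ marks the reference surface. Out-of-range particles are counted
and reported, never dropped; multi-frame profiles average densities, not
counts.

## Porosity

A sampling point in the unit cell is *occupied* when its minimum-image
distance to some framework atom is below $t \cdot r_{vdW}$ of that atom;
the default $t = 1/2$ follows the geometric pore-volume convention of
half the van der Waals radius, with $t = 1$ available (the two conventions
bracket the physically sensible range, and all bundled comparisons run at
the default). A point exactly at the threshold counts as void. The void
fraction is the Monte-Carlo mean of the indicator over uniform points,
with its binomial standard error; total void volume is
$\theta_{Gm} \cdot V_{cell}$. Minimum-image distances assume orthorhombic
cells; triclinic cells are out of scope.

The largest pore is located at the sampled void point with maximum
clearance, and a closed grid is fitted to its wall with a modified
weight: the geodesic Gaussian (width defaulting to one grid-cell arc at
the nearest-wall radius, $2\pi r_{near}/\mathrm{bin}$) multiplied by a
radial Gaussian centred on the smallest atomic radius in the node's
angular neighbourhood (width defaulting to the mean of $t \cdot r_{vdW}$,
one wall-layer thickness). The two exponents are combined and shifted
jointly in log space. The fitted wall radius minus $t \cdot r_{vdW}$ of
the nearest atom gives the void boundary; $D_P = 2 R_a$ of that grid is
reported together with the inscribed-sphere diameter (twice the maximum
clearance), since the two definitions differ for non-spherical pores.
The density power law is *not* used here: a cell-wide point set about a
pore seed has no meaningful surface density.

## Synthetic fixtures

`gen_surface_cloud()` samples directions uniformly in solid angle
(inverse-CDF on $\cos\varphi$, so poles are not over-represented) on
spheres, ellipsoids (radial-graph form) and sinusoidally modulated
spheres whose azimuthal terms are damped by $\sin^m\varphi$ so the radius
stays smooth and single-valued at the poles; the analytic radius function
accompanies every cloud. `gen_vesicle()` builds two concentric leaflets
with fixed per-lipid directions and optional smooth sinusoidal drift
across frames, plus index groups and closed-form per-frame truth.
`gen_porous_cell()` builds a cubic atom lattice with an optional carved
spherical cavity; when the thresholded exclusion spheres cannot overlap
(spacing $> 2 t r_{vdW}$) the void fraction is exact. Everything is
deterministic under its seed.

What these fixtures do *not* emulate: realistic lipid packing and
protrusions, atomistic roughness of pore walls, thermal disorder of
frameworks, or non-star-shaped (budding) vesicles. Passing tests
demonstrate correctness of the estimators on star-shaped closed surfaces
with known truth — not force-field realism. Surfaces that are not
star-shaped about the center violate the radial-graph assumption; the
volume routine warns when facets face inward.

* Sphere fixtures pin the center at the true center of the analytic
  surface, so all sampled radii are exact and the spherical limits
  ($S_C = 1$, roundness $= 1$) are reached to machine precision. Pipeline
  runs on PDB input estimate the center from the finite cloud, which
  leaves an $O(R/\sqrt{n})$ offset and correspondingly small departures
  (e.g. $S_C \approx 0.995$ for 600 lipids); the pipeline tests use
  tolerances that reflect this.

## Problem sizes and runtime choices

The bundled tests and the acceptance script run at sizes chosen for
seconds-scale runtimes while keeping statistical margins: clouds of
400–6000 points, bins 10–80, $10^4$–$10^5$ Monte-Carlo points per void
estimate, and a 64-atom analytic cell (4 nm cube) for the
sampling-density convergence check, where the expected deviation at
7 points/Å³ is ≈ 0.05% against the 0.1% bound. Densities or cells an
order of magnitude larger change none of the algorithms, only wall-clock
time; the fit is $O(\text{nodes} \times \text{atoms})$ in vectorized
matrix operations.

## Known limitations

* Radial-graph topology only: one value of $r$ per direction. Budding or
  toroidal shapes are outside the model.
* Orthorhombic periodicity for porosity; no CIF reader (PDB with CRYST1).
* Thickness assumes congruent bins and a shared center convention for the
  two leaflet grids.
* Roundness method 1 is a geometric convention (mean principal-plane
  cross-section perimeter); other circumference definitions would shift
  it by $O(\Delta^2)$.
* The colored-grid PDB writer clamps B-factors to the fixed-width column
  range $[-99.99, 999.99]$.
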