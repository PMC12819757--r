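---
title: "Methods: displacement-encoded MRI strain analysis of patellar cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: displacement-encoded MRI strain analysis of patellar cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartistrain)
```

# The measurement model

Stimulated-echo displacement-encoded MRI acquires one complex volume per
encoding direction in which the voxel phase is proportional to the tissue
displacement component along that direction and inversely proportional to the
encoding wavelength $\lambda$:

$$\varphi_d(\mathbf{x}) \;=\; \frac{2\pi\, u_d(\mathbf{x})}{\lambda},
\qquad d = 1, 2, 3 .$$

`cartistrain` fixes the proportionality constant exactly as above (positive
displacement gives positive phase); the hardware literature states only
proportionality, so this sign convention is a package convention, applied
consistently in both the phantom encoder and the decoder. The measured phase
is only available wrapped into $(-\pi, \pi]$: with $\lambda = 1$ mm, any
displacement beyond $\pm 0.5$ mm wraps at least once, so unwrapping is the
central inverse problem in the pipeline.

Axis conventions follow the anatomy: axis 1 is through-thickness (bone at
the bottom, articular surface on top), axis 2 longitudinal
(proximal-distal; proximal = larger coordinate), axis 3 transverse
(medial-lateral). All grids are voxel-centre, 0-based in world coordinates:
the world position of voxel $i$ (1-based in R) is
$\mathrm{origin} + (i-1)\cdot\mathrm{spacing}$.

# Pipeline stages

## Phase unwrapping

Each complex acquisition is optionally smoothed with a separable 3-D
Gaussian applied to the real and imaginary channels (phasor averaging, hence
insensitive to wrapping). Unwrapping is quality-guided region growing:

* quality = negative local variance of the wrapped phase gradients in a
  $3^3$ window — flat-phase neighbourhoods unwrap first;
* growth is 6-connected; each new voxel is shifted by the multiple of
  $2\pi$ closest to the mean unwrapped phase of its already-visited
  neighbours;
* ties in quality break by lexicographic voxel index, making the result
  bit-reproducible;
* disconnected mask components unwrap independently.

Unwrapping leaves one global constant per component undetermined (phase
encodes relative displacement only). The package resolves it with a
caller-supplied *zero-displacement reference region*: the median unwrapped
phase over the reference voxels of each component is subtracted and recorded
as `reference_offset`. Subtracting the full median (rather than only its
nearest multiple of $2\pi$) pins the reference region at exactly zero
displacement, which also removes any sub-$2\pi$ acquisition offset. On the
phantom the reference is bone immediately below the interface; on real data
the user supplies it.

The cartilage mask is dilated by a 3-voxel Euclidean ball before unwrapping
so boundary voxels with partial-volume signal participate; quantitative
comparisons are then restricted to the (eroded) tissue mask.

**Smoothing defaults.** The source workflow reports Gaussian smoothing but
not kernel widths; the defaults here are $\sigma = (1,1,1)$ voxels at the
complex stage and $(1, 0.5, 0.5)$ voxels for the assembled displacement
field (finer in-plane because those voxels are coarser: 1.5 / 2.0 mm vs
0.33 mm). Both are configuration parameters, not hidden constants, and the
correctness tests run the noiseless phantom with $\sigma = 0$: the kernels
exist for noise control and any nonzero width biases the recovered gradient
field slightly (about 10% peak attenuation at the defaults).

## From displacement to strain

Displacements are converted per component ($u = \lambda\varphi/2\pi$),
assembled into a vector field with masked smoothing (normalized by the
smoothed mask, so background never bleeds in), and trilinearly resampled
onto the anatomical grid. The Green-Lagrange tensor

$$E = \tfrac12\!\left(\nabla u + \nabla u^{\mathsf T}
      + \nabla u^{\mathsf T}\nabla u\right)$$

is computed along two routes:

* **mesh path (production)** — the cartilage mask is meshed with linear
  tetrahedra; nodal displacements are trilinear samples of the grid field;
  the per-element constant gradient comes from the shape-function
  derivatives; nodal tensors are obtained by *lumped-mass* $L_2$ projection
  (volume-weighted mean of adjacent elements). The lumped projection avoids
  a global solve, is exact for element-wise constant fields, conserves the
  volume integral of every component, and differs from a consistent-mass
  projection by $O(h)$ smoothing;
* **grid path (oracle)** — central differences on the voxel grid, one-sided
  at mask boundaries. Independent of all meshing code, it cross-validates
  the mesh path (the two agree to ~6% relative RMS in $E_\min$ on the
  full-size phantom; the suite enforces < 10%).

Principal strains are the eigenvalues of $E$ sorted descending,
$E_1 \ge E_2 \ge E_3$ (closed-form trigonometric solver, vectorized);
$E_\min = E_3$ (most negative eigenvalue) and
$E_{\max\mathrm{shear}} = (E_1 - E_3)/2 \ge 0$. Optional eigenvectors come
from symmetric `eigen()` per node with the sign fixed so the
largest-magnitude component is positive.

## Meshing

No isosurfacing or tetrahedralization library ships with this environment's
R stack, so both are implemented in the package:

* `extract_surface_mesh()` contours the Gaussian-smoothed mask indicator
  (isotropic lattice matched to the requested ~0.30 mm element size,
  indicator smoothing $\sigma = 1$ lattice voxel, level 0.5) with marching
  tetrahedra on a Kuhn (six-tets-per-cube) decomposition — watertight by
  construction. Crossing vertices within 30% of a lattice node snap to it
  (SnapMC-style), suppressing slivers; Taubin smoothing
  ($\lambda = 0.5, \mu = -0.53$) regularizes the staircase without the
  shrinkage of plain Laplacian smoothing. Triangles violating the quality
  thresholds (minimum angle > 15 deg, aspect ratio < 5, equiangle skewness
  < 0.7 — the source names the metrics but no limits; these are the
  package's thresholds) are remeshed by shortest-edge collapse with
  per-collapse watertightness validation, falling back to local one-ring
  relaxation where a collapse would violate the link condition. Meshes
  still failing are reported (`attr(mesh, "quality_ok")`), never silently
  accepted. The indicator is explicitly zeroed outside the source volume so
  a mask touching the volume edge still yields a closed surface.
* `build_tet_mesh()` fills a watertight surface with a Kuhn lattice whose
  cells span the bounding box exactly; cell centres are classified by
  ray-crossing parity (rays along axis 3, lattice jittered by an irrational
  sub-voxel offset so rays never hit edges). The boundary therefore follows
  the surface to within one cell rather than conforming exactly — volume is
  conserved to better than 10% on curved shapes and exactly on boxes.
* `tet_mesh_from_mask()` (used by the pipeline) lattices the mask directly
  after eroding it by half the cell body diagonal
  ($\mathrm{edge}\cdot\sqrt3/2$, anisotropy-aware): lattice nodes can sit up
  to that distance from a masked cell centre, and nodes outside the data
  mask would otherwise sample nearest-filled, gradient-flattened
  displacement. On the full-size phantom this erosion improves the
  mesh-vs-grid $E_\min$ agreement from ~31% to ~6% relative RMS.

## Graft analytics

* **Top view.** Each through-thickness column of masked voxels reduces to
  its 95th percentile (linear interpolation between order statistics, the
  `quantile` type-7 convention; nearest-rank is available since the source
  does not state which was used). Columns with no masked voxels are missing,
  never zero.
* **Step-off.** For each slice of the 1-2 plane intersecting the donor
  plug, the first and last axis-2 columns containing donor tissue are the
  distal and proximal crossings (proximal = larger axis-2 coordinate). In
  the adjacent recipient and donor columns, the start of subchondral bone is
  the first bone voxel scanning from the articular surface downward (the
  source wording is ambiguous about scan direction; this choice is then
  forced by the stated sign convention), and the step-off is the difference
  of those start depths — positive when the donor bone is elevated, negative
  when recessed, quantized to the 0.17 mm axis-1 voxel.
* **Strain pairs.** Outcome magnitudes are averaged over $3^3$-voxel
  neighbourhoods at matched mid-thickness depth, offset two in-plane voxels
  outside (recipient) and inside (donor) the interface. A neighbourhood that
  straddles the interface (e.g. near tangent slices) is reported as missing
  rather than contaminated. Percent change is
  $100\,(\mathrm{donor} - \mathrm{recipient})/\mathrm{recipient}$, undefined
  below a $10^{-6}$ denominator floor; note it is not antisymmetric under
  swapping the roles.
* **Fits.** Scatter of percent change against step-off with ordinary
  least-squares lines, proximal and distal arcs as separate series,
  explicitly descriptive (no inference attached — matching the source
  study's analysis posture).

# The synthetic phantom

No acquisition from the source study is deposited, so every end-to-end test
runs on a synthetic dataset with analytically known truth. The phantom is a
flat cartilage slab (thickness $t = 3.9$ mm) on rigid bone, indented at the
centre. The displacement is a smooth separable bump,

$$u_1 = -\delta\, g(r)\, \frac{x_1}{t}, \qquad
  u_{2,3} = \frac{\beta\delta}{\rho}\, g(r)\, \frac{x_1}{t}\, x_{2,3},
  \qquad g(r) = e^{-r^2/2\rho^2},$$

with $\delta$ the surface compression (0.25 / 0.50 mm), $\beta = 0.3$ a
radial bulge coefficient, and $\rho = \sqrt{R\delta}$ a Hertz-like contact
radius for the 12.7 mm indenter. This is *not* a contact-mechanics solution
— no analytic field exists for the real experiment — but it reproduces the
qualitative morphology (spherical through-thickness contours, lateral
bulging), vanishes identically at the bone interface, and has closed-form
derivatives, so the Green-Lagrange tensor is known exactly everywhere;
every derivative in the analytic strain is itself verified against central
finite differences in the suite. At the centre column the analytic
compressive strain is $E_{11} = -\delta/t + (\delta/t)^2/2 \approx -0.120$
at $\delta = 0.5$ mm, which anchors the strain-recovery checks.

The donor plug is a 9.5 mm-radius cylinder centred on the indentation axis
whose bone-cartilage boundary is tilted linearly,
$s(\mathbf{x}) = s_0 - s_1 (x_2 - c_2)/r_g$, so the rim trace is exactly
$s(\theta) = s_0 + s_1\cos\theta$ with $\theta = 0$ distal: the distal rim
is elevated and the proximal rim recessed, matching the directionality
reported for the cadaveric grafts. Default $s_0 = 0$, $s_1 = 0.5$ mm.

Encoded volumes are synthesized by evaluating $m\,e^{2\pi i u_d/\lambda}$ on
a supersampled lattice of the low-resolution grid (factors $2\times4\times4$,
sub-voxel 0.165 x 0.375 x 0.5 mm) and block-averaging the *complex* values,
which reproduces intravoxel dephasing. The paper's low- and high-resolution
grids are not integer-commensurate, so supersampling the low-resolution
lattice (at a density comparable to the anatomical grid) stands in for
averaging the literal high-resolution signal. Complex Gaussian noise is
added per channel with standard deviation (mean tissue magnitude)/SNR,
default SNR 30; magnitude images get Rician-style noise. Donor tissue gets
a slightly different magnitude intensity (segmentation contrast) but
identical mechanics. All randomness derives from the spec seed; identical
spec + seed is bit-identical.

**What the phantom does not emulate:** real patellar curvature, depth-dependent
cartilage material behaviour, fluid flow and time dependence,
B0/eddy-current phase errors, motion between encoding segments, and the
true (unknown) contact field under the indenter. Passing tests therefore
demonstrate that the *processing chain* is correct and self-consistent at
realistic geometry, resolution and SNR — not that the physiological strain
values of any particular specimen are reproduced.

# Numerical choices and degenerate inputs

* Gaussian kernels truncate at $4\sigma$; masked smoothing renormalizes by
  the smoothed mask, so constants are preserved exactly up to the border.
* Trilinear resampling refuses targets outside the source hull by default
  (`extrapolate = "clamp"` opts into nearest-edge extension); fields are
  nearest-filled outside their mask (capped sweeps) before interpolation so
  background zeros never mix in.
* `wrap_phase` maps half-integer boundaries up: $-\pi \mapsto \pi$.
* One-sided differences at mask boundaries in the grid oracle are first
  order by design; convergence tests therefore check the interior.
* Eigen ties (repeated eigenvalues) are handled by the closed-form solver's
  stable ordering; hydrostatic tensors give $E_{\max\mathrm{shear}} = 0$
  exactly.
* Empty masks, non-watertight or flat surfaces, inverted tetrahedra,
  bone-free columns, sub-voxel query offsets, and out-of-slab phantom
  queries all raise descriptive errors naming the offending entity.
* Percent-change denominators below $10^{-6}$ give `NA`, as do interface
  samples whose neighbourhood is not tissue-pure.

# Problem sizes

The test suite runs reduced grids (48 x 16 x 12 encoded, 72 x 64 x 64
anatomical, 24 mm slab) for module tests, and the full-size study grids
(96 x 32 x 24 and 196 x 128 x 128) for the acceptance checks; the mesh path
uses a 0.75 mm lattice (~117k tetrahedra) there. The whole suite completes
in under two minutes on one CPU; `scripts/acceptance.R` in about one.

# Known limitations

* The lattice tetrahedralizer approximates the surface to within one cell;
  it is not a conforming boundary mesh (acceptable here because strain is
  sampled from a voxel field, and mitigated by the erosion margin).
* The lumped $L_2$ projection smooths relative to a consistent-mass solve
  by $O(h)$.
* The unwrapping guarantees no global optimality: like all quality-guided
  region growers it can propagate errors across genuinely noisy regions;
  the SNR-30 study conditions are far from that regime.
* Bone is rigid and the graft mechanically identical to recipient
  cartilage; force prediction (which needs a constitutive contact model) is
  out of scope.
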