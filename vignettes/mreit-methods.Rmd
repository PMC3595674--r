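---
title: "Methods: simulation and harmonic Bz reconstruction in mreit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and harmonic Bz reconstruction in mreit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of a methods section: what is solved, under which
assumptions, with which defaults, and what the synthetic experiments do and
do not establish about real data.

## The imaging model

MREIT injects a current `I` through a pair of surface electrodes while an MR
pulse sequence runs. The current density `J = -sigma grad(u)` perturbs the
main field; its z-component `Bz` adds a phase `gamma * Bz * Tc` to the
complex MR image, where `gamma = 26.75e7` rad/T/s is the hydrogen
gyromagnetic ratio and `Tc` the current pulse width. Acquiring a second
image with the current reversed and dividing the two images cancels the
systematic phase artifact and doubles the current-induced phase:

    Bz = arg( M+ * conj(M-) ) / (2 * gamma * Tc).

With two independent injections the in-plane gradient of `ln sigma` is
determined by the 2D Laplacians of the two Bz fields through the matrix
`A = [(-Jy1, Jx1); (-Jy2, Jx2)]` of transverse current components:

    grad(ln sigma) = (1/mu0) A^-1 [lap Bz1; lap Bz2].

Taking the divergence gives a Poisson equation for `ln sigma`. The package
performs exactly **one pass** of this scheme with the reference conductivity
`sigma0 = 1`: the result is a *scaled* conductivity image, accurate in
contrast (not in absolute value) when the true contrast is low. This is the
deliberate scope — iterating to the absolute conductivity requires a 3D
forward machinery that is out of scope here.

Assumptions inherited from the one-pass 2D formulation:

* conductivity near the slice boundary is homogeneous (the phantom
  generator enforces a constant boundary ring and the reconstruction pins
  `sigma = 1` there);
* currents are translationally invariant across the slice (see the
  extrusion model below);
* conductivity contrast is low enough that `A[sigma0]` approximates
  `A[sigma]`.

## Forward simulation

**Phantoms.** `make_shepp_logan()` rasterizes ellipse tables (normalized
center/axes, conductivity in S/m) onto the pixel grid; later ellipses
overwrite earlier ones and the first defines the imaging domain. The default
table is a modified Shepp-Logan head with conductivities in [0.7, 1.4] S/m
around a 1 S/m background — contrasts representative of soft tissue.

**Forward solve.** The simplified 2D problem `div(sigma grad u) = 0` with
Dirichlet `u = ±1` on the electrode arcs and natural conditions elsewhere is
discretized with P1 finite elements on a pixel-conforming mesh and solved by
Jacobi-preconditioned conjugate gradients (tolerance 1e-10 for simulation).
Element conductivities are the pixel values themselves (the phantom is
piecewise constant per pixel); for meshes not aligned with the data grid,
bilinear sampling at element centroids is used instead. The current
amplitude enters only as a scale: `J` is rescaled so that a slab of
thickness `dz` carries the configured `I` (default 1 mA), which lands
`Bz` in the 1e-7 T range and the doubled phase near 1.8 rad for the default
`Tc = 30` ms — realistic, and sub-pi so the noiseless chain is testable
without unwrapping ambiguity.

**Biot-Savart.** `Bz` at the pixel centers is a discrete convolution of `J`
with the kernel of a z-extruded planar current. The default
`thickness_model = "infinite"` uses the translationally invariant kernel
`2/rho^2`, under which `Bz` is independent of z and the identity
`lap2 Bz = -mu0 (dJy/dx - dJx/dy)` holds exactly in the continuum; this is
the model under which a 2D-Laplacian reconstruction is consistent, and the
package's oracle tests (Laplacian vs. curl) rely on it. A finite slab kernel
(`"slab"`, thickness `dz`) is available; with it the in-plane Laplacian
omits the `-d2Bz/dz2` term and the identity holds only approximately. The
convolution is evaluated by FFT; within a 5-pixel near-field radius the
kernel is averaged over an 8x8 midpoint subdivision of the source pixel,
which also defines the singular self-pixel rule (its contribution vanishes
by antisymmetry of the midpoint subgrid). An optional affine background
field (harmonic, hence invisible to the Laplacian) can be added to test
invariance.

**MR synthesis.** `synthesize_complex_pair()` builds
`M exp(i delta) exp(±i gamma Bz Tc)` and adds independent circular complex
Gaussian noise per polarity, seeded. k-space uses DC-centered storage with
an unnormalized forward / `1/(nx ny)` inverse DFT; the convention travels
with the data and readers refuse to guess it.

## Phase processing

Unwrapping operates in the phase domain (before the `1/(2 gamma Tc)`
scaling) since the branch-cut algorithm is defined on `(-pi, pi]` data.
Residues are 2x2 loops whose wrapped differences fail to close; the variant
implemented pairs each residue greedily with its nearest opposite partner
(or the mask border when nearer; ties broken by scan order — fully
deterministic), rasterizes 8-connected cuts, and integrates by breadth-first
flood fill that never crosses a cut. A residue density above 10% of mask
pixels aborts with advice to denoise first.

After unwrapping, the additive `2*pi*k` per slice is fixed by moving the
median phase over the mask's boundary ring to the multiple of `2*pi` nearest
zero — `Bz` is physically near zero at the domain rim, and the choice only
shifts `Bz` by a constant, which the Laplacian kills anyway.

The z-continuity check compares the median absolute inter-slice difference
with the median in-plane per-pixel increment; a ratio above 5 (a
package-chosen default, exposed in the API) fails the pair and demotes the
Laplacian to 2D mode. The threshold is deliberately loose: it is meant to
catch per-slice unwrapping offsets (jumps of order `2*pi`), not mild
anatomy changes.

## Ramp-preserving denoising

Conductivity boundaries appear in `Bz` as *ramps* — slope changes, not
jumps. Plain smoothing rounds the creases and displaces the reconstructed
boundaries, so the denoiser diffuses along ramps but not across their
creases. The structure tensor is built from gradients of the gradient
components of `Bz` (second-derivative information): linear ramps carry no
tensor energy and are preserved structures, while creases concentrate it.
The diffusivity shares the tensor's eigenframe with eigenvalues
`1/(1+Lambda)` and `1/(1+lambda)`.

Defaults and their reasons:

* `T1` (total diffusion time, pixel units) is the single user knob, scaled
  to the noise level; 1-2 is typical for 1-5% noise.
* `T2 = 2` is the tensor regularization time; results are robust to it, so
  it is fixed.
* `s = 1` pixel is the Gaussian width for the tensor smoothing `Us`,
  truncated at `4s`.
* `dt = 0.2` respects the explicit stability bound `h^2/4` (diffusivity
  eigenvalues are at most 1, `h = 1` pixel); larger requests are clamped.
* The tensor is recomputed from the evolving field at every step (fully
  nonlinear). A frozen-coefficient mode (`refresh_tensor = FALSE`)
  evaluates it once on the initial field; the refreshed mode is the
  default because it keeps protecting creases as they sharpen.

**Scale convention.** `1/(1+Lambda)` is not scale invariant, and `Bz` in
Tesla would make every eigenvalue numerically zero. The tensor entering the
diffusivity is therefore rescaled so that the mean trace over the mask (of
the initial field) maps to `kappa = 5`. The constant was calibrated once on
the package's clean piecewise-ramp fixture: `kappa >= 5` keeps the maximal
pointwise change of a clean ramp profile under 1% of its range at `T1 = 1`,
while the seeded 5%-noise experiment retains strong denoising (the test
suite and acceptance script measure the RMSE ratios). It is a documented
convention, not a tuning knob, and is exposed as `kappa` for completeness.

The scheme is conservative by construction (face fluxes computed once and
differenced, no-flux at the mask boundary), so the mask mean is preserved to
roundoff and the centered L2 norm is non-increasing — both are enforced as
tests.

## Defect detection and harmonic inpainting

Where the MR magnitude is near zero the phase — and so `Bz` — is dominated
by amplified noise. Pixels below 10% of the maximum magnitude (per slice by
default; the fraction and per-volume alternative are exposed) are flagged
automatically, removing any user dependency from the repair. Under the
assumption that such voids are conductivity-homogeneous, `Bz` is harmonic
there, and the flagged pixels are refilled by solving the 5-point Laplace
equation with Dirichlet data from the surrounding valid ring (conjugate
gradients, tolerance 1e-10; defect islands inside other defects are simply
part of the joint system). A short isotropic diffusion (duration 2, matching
the magnitude of `T2`; "long enough" is not a sharp quantity) on the
one-pixel-dilated defect smooths the seam. The repair is idempotent for a
fixed mask and bit-exact outside it.

The defect mask is excluded from the denoising mask, and inpainting runs
after denoising so the rim data are clean: detection -> denoise (defects
excluded) -> inpaint is the fixed pipeline order.

## Geometry and meshing

The imaging domain is segmented from the MR magnitude by thresholding at
10% of maximum and tracing the largest closed iso-contour with
marching-squares (`contourLines`), simplified by Douglas-Peucker at half a
pixel. A level-set refinement of the outline is not implemented; for the
package's synthetic magnitudes the sub-pixel iso-contour is already accurate
(the test suite checks elliptical supports to 2% area).

Triangulations are built on a structured cell lattice: cells tiling the
polygon's bounding box (aligned to the pixel raster when a grid is given,
subdivided `k x k` when `max_area` demands sub-pixel elements) are kept when
their centers fall inside the polygon, and each is split into two positively
oriented triangles. No constrained-Delaunay library is used: all fields
(`sigma`, `J`, `Bz`, `lap Bz`) live on the pixel raster, so a pixel-
conforming mesh transfers data exactly and deterministically, at the price
that the mesh boundary is the staircase outline of the selected cells rather
than the polygon itself. Electrode markers propagate to boundary edges by
the perimeter parameter of the nearest polyline point (polygon path) or by
angular arcs about the domain centroid (mask path).

## Reconstruction

`lap Bz` uses the 5-point stencil with physical spacings (plus the
across-slice second difference in 3D mode, gated by the continuity report).
The validity mask is eroded by one extra ring beyond the stencil
requirement (`margin = 1`): the simulated `Bz` is only C^1 across the domain
boundary — the tangential current jumps to zero there — and stencils
touching the outermost ring pick up that boundary layer.

The matrix field `A` is built from the two `sigma0 = 1` forward solves;
points whose `|det A|` falls below `1e-3` times the median are flagged
unreliable and their right-hand-side contribution is zeroed (and counted in
the output). The Poisson problem for `ln sigma` uses the **weak form** of
the divergence right-hand side: `F = (1/mu0) A^-1 [lap Bz1; lap Bz2]` is
sampled at element centroids and integrated against test-function
gradients, which avoids differentiating the (noisy, already
twice-differentiated) data once more. The Dirichlet condition
`ln sigma = 0` on the region boundary is the default; the Neumann variant
(natural boundary condition with one pinned vertex) is available behind
`boundary = "neumann"` for completeness. No smoothing is applied to `F`
beyond what the denoising stage already did.

The local variant restricts the identical solve to a polygonal region `D`
with `ln sigma = 0` on its boundary. Its value is isolation: corrupted data
outside `D` cannot leak in through the global Poisson coupling. The
acceptance experiment emulates a corrupted annulus surrounding a clean
central region and compares the local solve against the restriction of the
global one.

The `mu0` division is a global multiplicative constant inside the gradient
of the log; it cannot change the contrast image and is applied by default so
that simulated physical units reconstruct `ln sigma` on its true scale.

## Numerical behavior and test scales

Unit tests run at 32-64 pixels; the oracle comparison against an
independent finite-difference forward solver runs at 160 (the discrepancy
between the two discretizations is dominated by the electrode-end
singularity and shrinks like 1/n), and the end-to-end experiments at
96-128 — sizes chosen so the full suite exercises the method at realistic
resolution while staying lean. Mesh refinement at a fixed data grid reduces
the homogeneous-phantom recovery error until the data-discretization floor
dominates (the refinement test asserts improvement from the first level and
saturation-no-worse at the finest); refining the *data* grid instead
sharpens the electrode-end singularity and does not reduce the max-norm
error.

## What the synthetic experiments do and do not show

The generator emulates the measurement chain faithfully in its phase model
(magnitude, systematic phase, current-induced phase, complex Gaussian
noise, k-space round trip) and in the forward physics of a 2D,
z-invariant current distribution. It does not emulate: genuinely 3D current
paths (real electrodes have finite height), chemical-shift and
susceptibility artifacts, eddy currents, RF inhomogeneity, or motion.
Passing the acceptance experiments therefore validates the computational
chain — not the 2D modeling error on a strongly 3D subject, which is a
physics question outside the package's scope. Scaled (not absolute)
conductivity is likewise intrinsic to the one-pass design.

## Known limitations

* Denoising and unwrapping are 2D, slice by slice; the 3D Laplacian is
  supported but 3D regularization is not.
* The mesh is pixel-conforming, not boundary-conforming; boundary staircase
  effects are confined to the outermost pixel ring, which the Laplacian
  margin excludes anyway.
* Goldstein unwrapping with dense residues (above 10%) is refused rather
  than attempted; denoise first.
* `segment_domain()` assumes the subject is the largest bright component
  and that a single closed contour describes it.
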