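---
title: "Modelling a semilunar-valve flow phantom: geometry, forcing, synthetic 4D flow and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a semilunar-valve flow phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvephantom)
```

## What this package models

`valvephantom` is a desk-scale model of a complete semilunar-valve
flow-phantom experiment: a parametric, 3D-printable aortic root with a
trileaflet valve; a pulsatile pump driving it against a hydrostatic
afterload; a time-resolved phase-contrast ("4D flow") acquisition over the
phantom lumen; and the retrospective flow analysis performed on such data
(through-plane flow waveforms, net and peak flow, regurgitant fraction,
sinus-vortex particle tracing). The velocity data are *synthetic*: the
package constructs an analytic, divergence-free flow field over the phantom
lumen and samples it the way a phase-contrast acquisition would, so every
quantification step can be validated against a closed form.

## Root geometry

The aortic root is described by named clinical dimensions (mm): annulus,
maximum sinus-of-Valsalva diameter, sinotubular junction, ascending aorta,
LVOT, plus wall and leaflet thicknesses (`root_params()`). The lumen radius
model is

$$ r(z,\theta) = r_{\mathrm{base}}(z)\,\bigl[1 + a\,\sin^2(\pi z/H)\,
   \max(0, \cos n\theta)^p\bigr], $$

where $r_{\mathrm{base}}$ blends the named diameters with cubic smoothstep
transitions, $H$ is the sinus height, $n$ the number of leaflets and $p$
(default 2) the bulge sharpness. The $\sin^2$ arch vanishes with zero slope
at the annulus and the sinotubular junction, keeping the surface $C^1$ —
with a plain $\sin$ arch the slope discontinuity at $z = H$ creates a
concave crease in which the outward wall offset self-intersects. The bulge
amplitude $a$ is not free: it is solved numerically (bisection to
$10^{-12}$) so the maximum lumen radius equals exactly half the prescribed
maximum sinus diameter.

The default dimension set (annulus 23 mm, sinuses 34 mm, sinotubular
junction 27 mm, ascending aorta 29 mm, LVOT 23 mm, sinus height 22 mm) is a
literature-typical normal adult aortic root; only the wall (2.0 mm) and
leaflet (0.6 mm) thicknesses are fixed by the phantom-fabrication
constraint. Every value is overridable, including from JSON, so bicuspid or
dilated-root variants are one parameter away.

### Wall shell

`build_root_mesh()` sweeps the lumen surface on an axial-by-circumferential
grid (defaults 120 x 192), offsets it outward by the wall thickness along
local surface normals, and closes the two rims with annular caps. The lumen
stays open for flow, so the printed *wall* is the closed solid: its boundary
surface is a genus-1 (torus-topology) closed 2-manifold with Euler
characteristic 0, while each leaflet shell is genus 0 with characteristic 2.
Orientation is repaired explicitly: a breadth-first parity propagation makes
the winding consistent per connected component, then any component with
negative signed volume is flipped, so exported STL normals always point out
of the material.

### Leaflets

The leaflet mid-surface is a loft in cylindrical coordinates between the
U-shaped attachment curve, which lies exactly on the root inner wall, and
the free edge. In the closed state the free edge follows the Y-shaped
coaptation pattern seen from above: two radial segments from the
commissures to a near-axis nodule, joined by a tangent-matched quadratic
rounding (corner radius about 2 mm). An earlier single-Bezier design pulled
the free edge outside the leaflet sector near the commissures and folded
the loft; the segment construction keeps the curve inside its sector and
the offset shell embedded. A gentle downward belly gives the closed leaflet
its concave-from-above curvature. Thickness is applied by offsetting the
mid-surface by half the leaflet thickness along its normals and sealing the
rim with a quad band. Leaflet $k$ is the canonical leaflet rotated by
$2\pi k/n$, so $n$-fold symmetry of the assembly is exact by construction.

Because shells have finite thickness, the free-edge *mid-curves* of
adjacent closed leaflets cannot meet within a fraction of a millimetre
without the shells interpenetrating; the coaptation tolerance is therefore
set to two leaflet thicknesses (1.2 mm for the default 0.6 mm leaflet),
which the closed assembly satisfies with margin. Valve opening is purely
kinematic — a blend between the closed free edge and a wall-hugging open
free edge, parameterised by an opening fraction — because leaflet dynamics
in the physical experiment are observed, not computed.

### Printability diagnostics

`mesh_diagnostics()` reports watertightness (edge-manifold plus consistent
orientation), Euler characteristic, signed volume, and a minimum shell
thickness measured by casting a ray from each face centroid along the
inward normal to the *opposite* shell surface (a hit counts only if its
outward normal opposes the source normal; this excludes rays that graze
corner bands, which would otherwise report the corner chord rather than the
shell thickness). Rays are pruned with a uniform spatial bucket and capped
at 4000 deterministically strided source faces — for uniform-thickness
shells the subsampled minimum equals the full minimum. On the default
meshes the root wall measures 2.00 mm (median) and the leaflet shell
0.58-0.60 mm; the minimum sits ~3% below nominal where the loft twists near
the commissures and vertex normals deviate slightly from face normals.

## Pump forcing and afterload

The programmed pump waveform is modelled as a half-sine systolic lobe,

$$ q(t) = Q_{\mathrm{peak}} \sin(\pi t / T_{\mathrm{sys}}), \qquad
   0 \le t \le T_{\mathrm{sys}}, $$

zero in diastole, with an optional negative dicrotic lobe immediately after
systole (`dicrotic_backflow_fraction`, default 0). The three numbers that
characterise the bench forcing — peak 100 mL/s, 60 beats/min, cycle-mean
27.74 mL/s — leave one free shape parameter, the systolic duration, which
`calibrate_systolic_duration()` solves from the closed form
$\bar q = 2 Q_{\mathrm{peak}} T_{\mathrm{sys}} / (\pi\,\mathrm{period})$,
giving $T_{\mathrm{sys}} = 0.4357$ s for the defaults. Cycle means are
computed by trapezoidal quadrature on 1000 samples per cycle with periodic
closure (relative error well below $10^{-4}$ for these smooth lobes); the
peak is evaluated at the analytic argmax $T_{\mathrm{sys}}/2$ carried by
the waveform object, so it does not depend on the sample grid containing
that instant. The open-circuit afterload converts a water-column height to
mmHg with the fixed density ratio 13.5951 (1088 mm of water = 80.0 mmHg);
temperature corrections are out of scope.

## Synthetic phase-contrast velocity data

`sample_velocity_field()` evaluates an analytic field at voxel centres and
frame centres (frames uniform over one cycle, instantaneous samples — no
view sharing or temporal blur). The axial jet over the core radius
$R(z)$ (the $\theta$-minimum lumen radius, i.e. the tube without the sinus
pockets) is parabolic by default,

$$ v_z(r,z,t) = \frac{2 q(t)}{\pi R(z)^2}
   \Bigl(1 - \frac{r^2}{R(z)^2}\Bigr), $$

carrying exactly the flux $q(t)$ through *every* axial plane. The radial
component is the exact solution of the continuity equation for this
profile,

$$ v_r = \frac{2 q}{\pi R^2}\, R'(z)\, \frac{r}{R}
   \Bigl(1 - \frac{r^2}{R^2}\Bigr), $$

(obtained from $v_r = -\tfrac1r \int_0^r s\, \partial_z v_z \, ds$; the
frequently quoted shortcut $v_r = -\tfrac r2 \partial_z v_z$ is not an
exact continuity solution when $R$ varies with $z$ and would leave a
residual divergence). A plug profile is available as a configuration
switch; Womersley profiles are a deliberate non-goal since the parabolic
closed form is what the quantification oracles integrate exactly.

Fluid in the sinus pockets outside the core is stagnant except for the
vortex term. The jet therefore has an idealised shear layer — a velocity
gradient discontinuity — on the surface $r = R(z)$ within the sinus
segment. The analytic field is divergence-free everywhere else, and
`field_divergence()` checks the discrete central-difference divergence on
interior voxels (lumen mask eroded twice, excluding a two-voxel band
around the shear surface), where it converges as $O(h^2)$ under grid
refinement.

### Sinus vortices

Each sinus hosts one Gaussian-core vortex, constructed as
$\mathbf v = \nabla g \times \hat e$ with
$g = C e^{-|\mathbf x - \mathbf c|^2 / 2\sigma^2}$ and $\hat e$ the local
circumferential direction, so the swirl lies in the radial-axial plane of
the sinus and the term is solenoidal by construction. The prefactor $C$ is
normalised so the circulation on the reference loop of radius
$\sqrt 2\,\sigma$ equals the prescribed strength (default 50 cm^2/s,
$\sigma$ = 2.5 mm, centre at mid-sinus height on the core surface — chosen
so the reference orbit stays inside the lumen). The vortex is gated on
smoothly when instantaneous flow falls below 5-15% of peak, i.e. during
diastole, which is when sinus vortices are physiologically expected.

### Phase-contrast encoding and noise

Velocity maps to phase as $\phi = \mathrm{wrap}(\pi v / v_{enc})$ on the
half-open interval $(-\pi, \pi]$, and back as $\phi\, v_{enc}/\pi$. The
round trip is the identity for $|v| < v_{enc}$; beyond it velocities alias
by multiples of $2 v_{enc}$, and exactly $\pm v_{enc}$ decodes to
$+v_{enc}$ under the half-open convention (fixed and tested). Default vencs
are 100 cm/s for the 4D protocol and 70 cm/s for the 2D protocol. Gaussian
noise of configurable SD is added per component per voxel inside the lumen
only, under a caller-supplied seed with the global RNG state restored.
Datasets interchange as one 4D NIfTI per component plus mask and a JSON
manifest (venc, frame times, grid origin, units, vortex metadata).

The default grid is a desk-scale 64^3 matrix covering the lumen with a
3 mm margin (about 0.63 mm laterally, 1.3 mm axially) and 20 frames per
cycle; the full-protocol matrix sizes remain available through
`acquisition_params()`. Voxel membership is a voxel-centre test; partial
volume effects are a non-goal.

## Flow quantification

`plane_flow()` integrates $\sum (\mathbf v \cdot \hat n)\, \Delta A$ over a
square lattice (default pitch 0.2 mm) masked by the interpolated lumen
(membership at interpolated mask >= 0.5), with trilinear velocity
interpolation; units work out as cm/s x mm^2 / 100 = mL/s.
`quantify_plane()` derives the scalar metrics: net flow is the *cycle-mean
flow rate* in mL/s (matching the units in which pump output is programmed),
peak flow is the maximum of the per-frame plane waveform, and
forward/backward volumes (mL) come from sign-split trapezoidal integration
with periodic closure, giving the regurgitant fraction. Plane placement
defaults to 10 mm proximal and 30 mm distal of the annulus — a
representative choice of "proximal and distal to the valve" stations — and `conservation_check()`
reports their relative net-flow difference, which is <= 2% on the
noise-free synthetic dataset (0.03% at default resolution) and degrades
monotonically in expectation with added noise.

Pathlines integrate $d\mathbf x/dt = \mathbf v(\mathbf x, t)$ with
classical RK4 (default step period/200), trilinear in space and linear in
time between frame centres with periodic extension, terminating with a
recorded status on leaving the lumen or the grid (a seed outside the grid
terminates immediately rather than raising). Vortex capture is quantified
by the winding number of a trajectory about the vortex core, and
`sinus_circulation()` measures the velocity line integral around a
configurable loop in the swirl plane, traversed right-handed about the
vortex axis; on the synthetic field it recovers the prescribed strength
within 5% (interpolation being the only error source).

## Numerical choices and degenerate inputs

* Bulge amplitude: bisection on the profile maximum, tolerance 1e-12 mm.
* All-equal diameters degenerate to a straight tube (amplitude exactly 0);
  this fixture exercises every stage and is part of the test suite.
* Mesh welding tolerance 1e-9 mm; STL import welds float32-identical
  vertices to recover connectivity.
* Ray-cast thickness: first hit beyond 1e-6 mm, excluding faces sharing a
  vertex with the source, requiring an opposing-normal hit (dot <= -0.5).
* Quadrature: trapezoid with periodic closure everywhere a cycle integral
  appears; waveform default 1000 samples/cycle.
* Seeds: every stochastic element (noise) takes an explicit integer seed;
  fixed seed implies byte-identical pipeline outputs.

## Problem sizes

The shipped defaults are deliberately desk-scale: 64^3 voxels x 20 frames
for the synthetic dataset (about 126 MB of velocity data in memory),
120 x 192 root mesh (~93k faces), 64 x 32 leaflet grids, 0.2 mm plane
sampling, and 4000-ray thickness diagnostics. The full pipeline runs in
seconds to a couple of minutes on one CPU. Test fixtures scale these down
further (32^3 grids, 10 frames).

## What the synthetic data do and do not show

Passing tests demonstrate that the *software* — geometry, encoding,
quantification, tracing — is internally consistent and agrees with closed
forms: flux conservation, divergence-freeness, aliasing arithmetic, RK4
orbit accuracy, mesh topology. The synthetic fields do not emulate MR
physics beyond velocity-to-phase encoding (no k-space, no acceleration
artefacts, no eddy-current or Maxwell terms, no background phase), nor
fluid-structure interaction of the leaflets, nor turbulence or realistic
shear-layer thickness. Agreement of the toolkit with its oracles therefore
validates the analysis chain, not the hemodynamics of any physical phantom;
in-scanner measured values from physical experiments are intentionally not
reproduction targets, and the corresponding consistency *properties* are
what the acceptance suite checks.
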