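---
title: "Models and numerics behind ctcchip"
author: "ctcchip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind ctcchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctcchip)
```

`ctcchip` simulates, in two dimensions, a microfluidic biochip with two
serial subunits: a diverging channel that pulls immunomagnetically tagged
circulating tumor cells (CTCs) onto its bottom wall with a permanent magnet,
and a Y-channel mixer that blends the CTC-enriched stream with lysis buffer
by AC electroosmosis. This vignette records the governing models, the
numerical choices, and the reasoning behind every parameter the device
description leaves open. It states no result that the package's test suite
and acceptance script do not themselves compute.

## Device geometry and coordinates

The separator inlet is 500 µm wide and runs 3 mm before a 2 mm-long
diverging passage takes the channel to 2 mm width; the wide section is 7 mm
long and ends in a 500 µm top outlet (untagged cells) and a 700 µm bottom
outlet (tagged cells). The expansion is on the bottom side: x runs along the
channel from the inlet mouth, y is transverse with y = 0 at the inlet's
bottom wall, so the wide section spans y ∈ [−1.5, 0.5] mm and the magnet
below the chip pulls cells into the widened region. Two variants exist:
`separator_prompt` (right-angle step) and `separator_gradual` (linear taper);
they differ in area by exactly the taper triangle, ½ · 2 mm · 1.5 mm, which
the tests assert from the polygon areas.

Dimensions the description leaves open are config parameters with these
defaults: a 500 µm ancillary inlet joins the bottom wall perpendicularly,
centered 1 mm upstream of the taper; the bottom outlet width (700 µm) stands
in for the outlet sizing the magnet study informs; the mixer's two Y-arms
are represented as the two halves of the left boundary of the 9 mm × 1 mm
channel (the oblique arms themselves carry no physics of interest here).

## Flow solver

Steady incompressible flow (continuity plus momentum, Newtonian, laminar) is
discretized with finite volumes on a staggered (MAC) grid: velocities on
faces, pressure in cells, the geometry rasterized to a cell mask so oblique
walls become staircases. The coupled velocity–pressure saddle system is
assembled sparsely and solved by direct LU (`Matrix`); the convective term
is added by Picard iteration on the Oseen linearization (relative-change
tolerance 1e-8, at most 30 iterations; a `stokes` switch drops it).
Boundary conditions per labelled segment: velocity inlets with a parabolic
(fully developed) profile — the channels are far longer than the entrance
length at Re ≤ 20 — fixed-pressure outlets (0 Pa on both separator outlets,
so the flow split between them is an outcome, not an input), and walls with
optional prescribed tangential slip for the electroosmotic mixer.

Tangential wall values enter through quadratic ghost extrapolation, which
reproduces quadratic profiles exactly: the plane-Poiseuille checks in the
test suite pass at machine precision rather than at a truncation-limited
tolerance. Mass conservation is inherited from the direct solve (a 1e-12
pressure regularization keeps the LU robust when no outlet pins the
pressure level); the tests bound the discrete divergence by
1e-8 · U/L and the net boundary flux by 1e-10 of the through-flux.

The stabilized finite elements commonly used for this device class
(streamline/crosswind diffusion, quadratic velocity with linear pressure
elements) are deliberately not reproduced: at Re ≤ 20 on these
grids a standard central scheme is stable, and functional equivalence — not
element fidelity — is the contract. Recirculation is detected by the sign
criterion (a connected patch of cells with axial velocity reversed against
the bulk, above a 3-cell floor), which is corner-sensitive; the default
separator grid (240 × 40, 50 µm cells) keeps ≥ 8 cells across the taper.
Tests run on 120 × 20 for speed, which still resolves the step vortex.

## Magnetostatics

The permanent magnet is a uniformly magnetized rectangle. The analytic field
is the equivalent surface-charge solution: magnetization M jumping to zero
across a face is a magnetic surface charge M·n, and each face is a charged
line segment with closed-form H. Inside the magnet B = μ0(H + M); outside
B = μ0 μr H. The tests check the interface conditions (normal B and
tangential H continuous across faces), mirror symmetry, the 2D line-dipole
r⁻² far field, and ∇·B = 0.

An independent numeric oracle solves ∇·(−∇Vm + M) = 0 for the scalar
potential on a padded grid (padding ≥ 5 magnet sizes enforced). Two details
matter for the 2% agreement contract: the far-field Dirichlet boundary uses
the line-dipole asymptotic of the potential rather than zero (a grounded box
at 6 magnet sizes would alone contribute several percent), and the face
charges are deposited onto grid nodes with linear (cloud-in-cell) weights so
the source is second-order accurate in the face position. With n = 320
nodes per direction the analytic and numeric fields agree to well under 2%
relative |H| on probe sets away from the faces.

The magnetophoretic force uses the gradient of |H|²; a literal vector
Laplacian is dimensionally inconsistent with a force and the magnetic
buoyancy form F = 2π rp³ μ0 μr K ∇|H|² with the permeability contrast
K = (μr,p − μr)/(μr,p + 2 μr) is the standard reading. Magnet dimensions and
standoff are not fixed by the device description; the defaults (2 mm × 2 mm
block,
y-magnetized at 750 kA/m, 0.5 mm below the bottom wall) make the field decay
appreciably across the 2 mm channel, and the peak |B| on the channel-side
face is asserted only to the order-of-magnitude band 0.5–1.5 μ0M.

## Particle dynamics

Tagged cells are effective spheres (10 µm, 1050 kg/m³) with relative
permeability 1.15 from the bound beads; untagged cells have μr,p = μr, hence
K = 0 and no magnetic response. Coupling is one-way (volume fraction
below 1%).

Drag follows Schiller–Naumann, handled through the product CD·Re so the
Stokes limit is exact: τp → ρp dp²/(18 μ) = 5.83 µs at zero slip. The
response time is τp = 4 ρp dp²/(3 μ CD Re), the form that recovers Stokes
drag 3π μ dp U; a compatibility variant with prefactor 2/3, whose
low-Re limit is half the Stokes value, is available as
`correlation = "half_response"` for comparison with reports that use it.

Because τp (microseconds) is far below the transit time (seconds), the
default integrator is the overdamped force balance v = u + F/(3π μ dp φ),
with the drag correction φ resolved by fixed-point iteration and RK4 on
dx/dt = v(x); the full inertial momentum equation (RK4, dt ≤ τp/2 enforced)
is retained for validation, and the tests check both against the closed-form
drift line in uniform flow and their mutual convergence. Wall capture uses
segment-crossing detection with bisection to the boundary; a particle is
captured only where an attractive external force exists (K ≠ 0 or gravity
enabled) — force-free tracers that graze the staircase boundary numerically
are held inside, which keeps the tracer-limit equivalence with streamlines
exact in statistics. Gravity and buoyancy are excluded from traces by
default: the force audit evaluates (4/3)π Rc³ ρ g = 5.13 pN (ρ = 1000) and
5.39 pN (ρ = 1050) against a magnetophoretic force two orders larger near
the magnet, and classifies by a 1%-of-maximum threshold. These two
reference magnitudes are sometimes quoted with their labels swapped (the
ρ = 1050 evaluation is necessarily the larger); the audit computes both so
the ordering is explicit. DLVO, Brownian and inter-particle forces are
excluded by
assumption (dilute, surface-treated suspension) and only reported
qualitatively.

## Mixer electrokinetics

The ten electrodes are 0.6 mm long with 0.6 mm same-wall gaps, zigzag
(alternating walls, staggered by half a pitch) from 1 mm downstream of the
junction — the staggered arrangement the device sketches show, with the
dimensions left to the model. Adjacent
electrodes along the channel are driven in antiphase, sign (−1)^(k+1), with
V(t) = V0 sin(2πft). The quasi-static potential solves ∇·(σ∇V) = 0 with
V = ±1 on electrodes (unit mode, scaled by the drive), zero normal current
elsewhere, and no impressed currents or sources — the only physically
sensible closure for this device. The tangential wall field is obtained by
extrapolating the potential to the wall and differencing along it; the
Helmholtz–Smoluchowski slip uT = −(εw ζ0/η) Et (ζ0 = −0.1 V, εr = 80
assumed) is applied on all wall segments, electrodes included
(thin-double-layer idealization; on electrode surfaces the tangential field
is small anyway since the potential is clamped).

### Time-periodic flow and the frequency optimum

Linearity of the Stokes regime lets the time-dependent flow be one
pressure-driven base solve plus one electroosmotic mode. The default mode is
the **harmonic response of the unsteady Stokes equations**
(iωρ û = μ∇²û − ∇p̂, solved as a real 2×2 block system for the in-phase and
quadrature parts): the fluid has a finite viscous response time
(ρW²/μ ≈ 1 s for the 1 mm channel, with the slip-driven vortex structures
responding on ~0.1 s scales), so above a corner frequency the bulk no longer
follows the drive and the actuation amplitude falls — the mechanism the
source invokes for mixing deteriorating at high frequency. A quasi-steady
mode (steady slip solve scaled by the instantaneous waveform) is available
as `unsteady = FALSE`; it is exactly what the superposition-oracle test
verifies against per-time direct re-solves. The base-flow Reynolds number is
guarded (warning above 1): the harmonic model neglects convective coupling,
including steady streaming, at the default operating point (base Re ≈ 6,
slip-velocity Re ≈ 36) — a known limitation of the superposition approach.

The mixer inlet mean velocity defaults to 6 mm/s. The value is fixed by the
device itself rather than assumed freely: the integrated chip feeds mixer
inlet A from the separator's bottom outlet, and solving the separator at its
stated conditions (10 mm/s main, 4 mm/s ancillary inlet) delivers a
bottom-outlet mean velocity of ≈ 6.3 mm/s. This choice matters physically:
it sets the residence time of fluid parcels in the electrode region, and the
frequency optimum of a flow-through oscillatory mixer is a competition
between stirring cycles per residence time (favoring high f) and stroke
amplitude per cycle (favoring low f, and additionally attenuated by fluid
inertia at high f). At a much slower base flow the stroke term dominates at
every studied frequency and the optimum degenerates to the lowest frequency.

### Scalar transport and the mixing index

The concentration (c = 1 on the CTC-stream arm, 0 on the lysis-buffer arm,
initially the unmixed parallel-stream stratification) is advanced by
explicit conservative finite volumes: MUSCL/minmod limited upwind convection
— second order away from extrema, TVD, hence maximum-principle preserving
under the CFL bound (checked and auto-reduced) — plus isotropic diffusion
(D = 1e-10 m²/s assumed). Plain first-order upwind was rejected because its
numerical diffusivity (~u h/2, three orders above D on the 128 × 24 grid)
dominated the mixing physics. Walls are no-flux, the outlet advective;
during flow reversal the outlet re-entrains its own zero-gradient profile.

Mixing quality is the coefficient of variation of n = 100 pixels sampled on
a transverse line 0.5 mm upstream of the outlet: CoV = sd(ci)/mean(ci) with
the n−1 denominator, M.I = 1 − CoV (so a perfectly mixed line gives exactly
1, and an unmixed half/half line with n = 100 gives −0.005). The mass
average and the arithmetic mean coincide for uniformly spaced pixels; the
arithmetic mean is used. Since the instantaneous index
oscillates with the drive, sweeps report the time average over the last
actuation period of the 2 s horizon.

## Synthetic ensembles: what they emulate and what they do not

`seed_particles()` stands in for the spiked, pre-centrifuged blood sample:
deterministic placements (three tracers at 10/50/90% of the inlet width;
uniform ensembles at bin midpoints with a 2% wall clearance), initial
velocity equal to the local fluid velocity, a stored integer seed, and
optional jitter (off by default) as the only randomness. Real samples differ
in ways the model deliberately omits: cell size and density dispersity,
variable bead load (hence variable K), Brownian motion, near-wall drag
corrections, cell–cell interactions, and adhesion chemistry on the wall. A
passing suite therefore validates the transport model under the stated
idealizations, not capture efficiencies of a physical device.

## Problem sizes and runtimes

Defaults: separator 240 × 40 cells, mixer 128 × 24, numeric magnet oracle
320², tracing dt = 0.2 ms with a 2–6 s horizon. The test suite runs the
separator on 120 × 20 and traces with dt = 0.4 ms; these sizes keep every
qualitative contract (taper resolution, vortex detection, interior
dispersion minimum) while completing in minutes. The acceptance script runs
the full mixer pipeline at the default 128 × 24 grid for the four studied
frequencies.

## Known limitations

Two-dimensional throughout (no top/bottom wall drag, so flow rates per unit
depth); staircase walls on structured grids; one-way coupling only; fixed
zeta potential (no capacitive electrode charging, so no intrinsic ACEO
frequency response beyond fluid inertia); superposition neglects convective
coupling of base and oscillatory flow; no Joule heating; no cell lysis
chemistry; no quantitative shear-viability criterion for cultured cells.
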