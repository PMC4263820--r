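---
title: "Methods: a fibril-reinforced biphasic contact model of tibiofemoral creep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fibril-reinforced biphasic contact model of tibiofemoral creep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(poroknee)
```

## What the package models

Articular cartilage and meniscus are biphasic: a porous, fibril-reinforced
solid skeleton saturated by interstitial fluid. Under a suddenly applied
joint load the fluid cannot escape instantly, pressurises, and carries most
of the contact stress; as it seeps out through permeable boundaries the load
is gradually transferred to the solid matrix and the joint creeps. `poroknee`
simulates this process in an idealised two-dimensional coronal cross-section
of the tibiofemoral joint, in an intact configuration and after double
meniscectomy, under a ramp-hold body-weight protocol (800 N applied over
1 s, then held for 1200 s, applied 5 mm medial of the joint centre —
statically equivalent to a centred load plus a 4 N m adduction moment).

The quantities the analysis reports are the femoral settlement, contact
areas per interface and compartment, the split of load between the
meniscus-borne and direct cartilage-cartilage paths and between the medial
and lateral compartments, the peak compressive (most negative principal
total) stress, and fluid pressure and fluid load support at probe points on
the tibial surface.

## Constitutive model

Each tissue is a fibril-reinforced biphasic continuum in the
N-mm-s-MPa unit system:

* **Non-fibrillar matrix** — linear isotropic elasticity with drained
  Young's modulus $E$ and Poisson's ratio $\nu$ (Lamé constants
  $\lambda,\mu$; aggregate modulus $H_A = \lambda + 2\mu$). The tissue
  presets are femoral cartilage ($E$ = 0.64 MPa, $\nu$ = 0.08), tibial
  cartilage (0.84, 0.03) and meniscus (1.0, 0.03).
* **Collagen fibrils** — one in-plane tension-only family per element:
  $\sigma_f = E_f \langle \varepsilon_f \rangle \, d \otimes d$ with
  $\varepsilon_f = d^\top \varepsilon d$. Cartilage fibres run tangent to
  the articular surface ($E_f$ = 5.6 MPa); meniscal in-plane fibres are the
  radial family ($E_f$ = 10 MPa).
* **Fluid** — Darcy flow $w = -k \nabla p$ with constant permeability
  ($k$ = 1.16e-3, 3.26e-3 and 1.0e-3 mm$^4$/(N s) for femoral, tibial and
  meniscal tissue), and the biphasic stress split
  $\sigma_{tot} = \sigma_{eff} - p I$ (stress tension-positive, pressure
  compression-positive).

Two deliberate simplifications relative to finite-deformation
fibril-reinforced models: the matrix is linear (small strain) and the
fibril law has no strain-stiffening toe region. Both are appropriate only
because the load intensity is scaled into the small-strain regime (below).

## Discretisation and time stepping

The coupled equations — quasi-static solid momentum
$\nabla\!\cdot\!\sigma_{tot} = 0$ and fluid continuity
$\partial_t(\nabla\!\cdot\! u) = \nabla\!\cdot\!(k\nabla p)$ — are
discretised with 9-node biquadratic displacement / 4-node bilinear pressure
(Taylor-Hood) quadrilaterals, which satisfy the inf-sup condition in the
nearly incompressible instantaneous limit, and integrated with backward
Euler (first order, unconditionally stable, monotone creep without
oscillation). Each step solves the symmetric indefinite saddle system by
direct sparse factorisation; the output grid (end of ramp plus 20
log-spaced hold times) is hit exactly, with adaptive step growth (factor
1.6 up to 50 s) between output times and step halving on failure.

Verification rests on two closed-form oracles shipped as public API:

* one-dimensional confined-compression creep (series solution with gel
  diffusion time $t_g = h^2/(H_A k)$): the FE column (20 elements)
  reproduces the surface settlement within 2% relative $L_2$ error over
  $[0.01, 3]\,t_g$;
* the unconfined plane-strain strip between frictionless impermeable
  platens: the instantaneous apparent stiffness approaches the
  incompressible limit $4\mu$ (within 5%) and the drained equilibrium
  stiffness $E/(1-\nu^2)$ (within 2%).

## Synthetic joint geometry

The geometry module generates what the analysis needs and nothing more: a
flat-topped tibial cartilage layer (bottom fully fixed to the rigid tibia),
two circular condylar cartilage arcs whose inner surface is rigidly coupled
to the femur (free vertical translation and varus-valgus rotation;
transverse translation and flexion rotation fixed), and, in the intact
variant, two meniscal wedges resting unbonded on the tibial surface. The
wedge top follows the condyle arc at a small clearance — the menisci render
the unloaded joint congruent — while the direct cartilage-cartilage gap at
the condyle apex is larger (`central_clearance`, default 0.4 mm): the
unloaded cartilage surfaces are incongruent and first contact passes
through the menisci, which is what makes the meniscal path carry the
majority of the load at load application. All geometry values are free
model parameters, not subject-specific measurements.

Three geometric choices deserve comment:

* **Hoop tension.** The meniscal circumferential fibrils (40 MPa) act out
  of plane and cannot be represented by an in-plane fibre tensor. Their
  hoop-tension effect is modelled as a distributed horizontal elastic
  foundation over the wedge cross-section with stiffness density
  $E_{circ}/(R_{ring} L_{horn})$ (plus a weak vertical foundation, 5% of
  the horizontal density, that suppresses the rigid and rocking modes of
  the frictionally unrestrained wedge). The effective horn free length
  $L_{horn}$ = 5 mm puts the radial extrusion under body weight in the
  physiological 1-3 mm range. This is the module's largest idealisation.
* **Tip relief.** The wedge's inner feather edge is relieved away from the
  condyle by 0.3 mm over the inner quarter of its width. A drained,
  frictionless feather edge in direct contact would collapse under the
  condyle (a small-strain model has no finite-deformation stiffening to
  stop it); anatomically the inner rim is not in compressive contact in
  the unloaded joint.
* **Load intensity.** The package deliberately pairs small-strain
  kinematics with a reduced load intensity — a linear tissue under the full
  per-depth body-weight pressure would be driven to strains far outside the
  model's validity. The out-of-plane depth (default 125 mm) maps
  the 800 N protocol to 6.4 N/mm of section depth, which keeps drained
  compressive strains near 15% (intact) and 30% (meniscectomy). The
  qualitative mechanisms — creep, load redistribution, fluid support —
  are preserved; absolute magnitudes are not comparable to the
  three-dimensional joint.

The meniscectomy variant removes the wedges and keeps every other
coordinate identical (same alignment as the intact joint); its femur first
travels through the unloaded clearance, and reported displacements start at
first cartilage-cartilage contact.

## Biphasic contact with a moving drainage boundary

Six contact pairs are defined for the intact joint (femoral-meniscal,
meniscal-tibial and femoral-tibial on both sides), two for the
meniscectomised joint. Contact is frictionless node-to-segment: the nodes
of the secondary surface (the cartilage side) are projected onto the
piecewise-quadratic primary surface, and the normal traction is the
penetration times the penalty factor. The penalty factor per pair follows a
deterministic auto-penalty rule, `scale * min(H_A)/segment length` with
scale 100.

Three regularisations make the step problem smooth, which the solver
exploits:

* the penalty law has a quadratic blend of half-width 2 um around first
  touch (continuously differentiable in the gap);
* a projection sliding past a surface end loses its force linearly over
  10% of the end segment (corner contacts appear and disappear
  continuously);
* the tension-only fibril law has a quadratic blend of half-width 1e-4
  strain.

Fluid boundary conditions on the contact faces follow the patch
automatically: a contact point genuinely in contact is sealed — its
pressure is tied to the interpolated pressure of the opposing surface by a
penalty on the pressure jump — while the open remainder of each contact
face drains freely (an ambient-conductance penalty drives p to 0). The seal
weight ramps smoothly across the contact blend zone, so the partition
moves with the patch edge. Suppressing this switching (forcing free
drainage everywhere, `drainage_switch = FALSE`) collapses the contact-face
pressure and is kept as a mechanism regression: the solutions differ
considerably when the contact-dependent conditions are omitted.

## The per-step solver

Within each backward-Euler step the contact geometry — feet, normals,
pairing, end fades — is frozen at the previous converged state, so each gap
is an affine function of the solution and the regularised contact and
fibril laws make the step system smooth with an exact tangent. A damped
Newton iteration (full steps while converging, factor 0.5 when increments
stall, rigid-body increments clipped to 0.5 mm) solves it to a relative
increment of 1e-6. The sealed/free-draining partition, whose gap
sensitivity is deliberately left out of the Jacobian, is refreshed each
time the mechanical iteration converges, and the step is accepted once a
refresh no longer moves the solution — the partition is then
self-consistent with the accepted state. Geometry and partition thus evolve
from step to step rather than inside the Newton loop; this is the package's
resolution of the moving-boundary problem and is the main reason the
iteration is robust. The price is a small step-to-step re-linearisation
noise (~0.01 mm in displacement, ~1% in area), visible as ripple on the
early-hold time series; the tests treat monotonicity claims with a
corresponding numerical-noise band.

Two tiny regularisation stiffnesses keep pre-contact configurations
nonsingular: grounded springs on the femur's two rigid DOFs (0.01 N/mm and
5 N mm/rad per unit depth) and the meniscal vertical foundation noted
above. At equilibrium their forces are far below 1% of the applied load.

## Probes and reported metrics

The "condyle centre" probe of each compartment is defined operationally as
the tibial-surface pressure node nearest the traction-weighted centroid of
the direct cartilage-cartilage patch at the end of the ramp, then tracked
as a fixed material point; the "meniscus interface" probes use the
meniscal-tibial patch in the same way. Probe pressure and total contact
traction are both read from one consistent Gauss-point field recovery of
the tibial layer (traction = $-\sigma_{yy}^{tot}$ at the flat surface):
point-sampled penalty tractions carry node-to-segment checkerboard noise
that would alias into the fluid support ratio (the pressure-to-contact-
pressure ratio can slightly exceed 1 for the same reason). Contact areas
are active contact length times the out-of-plane depth; compartment and
total areas follow the tibial-surface convention (cartilage-cartilage plus
meniscus-cartilage interfaces on the tibial surface). Interface forces
integrate the penalty tractions vertically; the meniscal path sums the
femoral-meniscal pairs and the compartment split sums the two femoral-side
interfaces per compartment, which balances the applied schedule within
solver tolerance at every output time.

## Problem sizes and defaults

The default joint mesh (element size 1 mm) has roughly 330 biquadratic
elements and 7,000 unknowns; a full 1201 s protocol solves in minutes on a
single core. The verification fixtures use 20 elements (column) and 8x4
elements (strip). Mesh refinement by a factor 2 changes the end-of-ramp
peak fluid pressure by under 5%, which is the package's convergence
criterion for the default density. The simulation is deterministic: no
random number is drawn anywhere in the solver, and regenerating a mesh from
identical parameters is bit-identical.

## What passing the tests does and does not show

The synthetic geometry reproduces the structural features the analysis
depends on — two compartments, a meniscus-borne and a direct load path, a
peripheral free-draining boundary, horn-anchored wedges — but not
subject-specific anatomy, three-dimensional contact patch shapes,
depth-dependent tissue inhomogeneity, ligaments, or finite-deformation
kinematics. Consequently the package's joint-level numbers (millimetres of
settlement, MPa of stress) are internally consistent model outputs, not
predictions for a physical knee; the mechanism-level statements — creep of
displacement and area, load transfer from the meniscal to the direct path,
stress concentration and area loss after meniscectomy, high and slowly
decaying fluid support at the covered condyle centres versus the
free-draining meniscal interface, offset-controlled compartment split —
are the claims the test suite actually verifies.
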