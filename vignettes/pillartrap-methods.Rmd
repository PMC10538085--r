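---
title: "Models and numerical methods in pillartrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in pillartrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pillartrap)
```

pillartrap models the capture of deformable cells in microfluidic traps
built from arrays of diamond-shaped pillars. A cell carried by the flow is
pressed against the gap between two pillars; if the driving pressure stays
below a critical value $P_c$ the cell is retained, otherwise it squeezes
through. This vignette documents the models behind each part of the
package, the tunable parameters, and the numerical choices, so results can
be interpreted and reproduced.

## The empirical critical-pressure relation

The closed-form model at the core of the package is a power law,

$$P_c = c\,E\,(a/g)^n,$$

with $a$ the cell diameter (µm), $g$ the gap (µm), $E$ the effective
whole-cell Young's modulus (Pa), and the published calibration $c = 0.027$,
$n = 2$ as the default `power_law_model()`. Two structural properties
follow immediately and are enforced throughout: $P_c$ is exactly linear in
$E$, and it depends on size only through the dimensionless ratio $a/g$.

`fit_power_law()` estimates $(c, n)$ from a table of
(modulus, diameter, gap, critical pressure) records. The default objective
is ordinary least squares on $\log P_c$: it linearises the power law and
weighs *relative* errors equally across pressure decades, which is the
appropriate loss when the response spans orders of magnitude. A
sensitivity alternative (`method = "nls"`) minimises untransformed squared
pressure residuals with a bounded Levenberg–Marquardt search, multi-started
at exponents 1, 2 and 3 and restricted to $n \in [0.5, 4]$ — a bracket
comfortably containing the linear-to-cubic range under comparison.
Goodness of fit is always reported on the untransformed pressure scale
($R^2 = 1 - SS_{res}/SS_{tot}$), because competing model orders are
compared on pressures; residual standard errors are reported on both the
log and pressure scales, since either convention appears in practice.
`compare_model_orders()` fits $n \in \{1,2,3\}$ and ranks by this $R^2$,
breaking ties in favour of the lower order (parsimony). Records with
$P_c = 0$ (free passage) carry no information about a multiplicative law
and are dropped with a warning.

`validate_against()` compares model predictions with measured
(gap, pressure) pairs: $R^2$ is computed about the identity line
(observed vs predicted), so a constant offset lowers $R^2$ while leaving
the Pearson correlation at 1 — the two statistics answer different
questions and both are returned.

## The hydrodynamic load on a trapped cell

The carrier flow is not resolved around the moving cell. Its push is
idealised as a parabolic pressure field applied to the upstream part of
the cell surface,

$$p(y, z) = P_0 \left(1 - \frac{y^2 + z^2}{r^2}\right),$$

peaking at $P_0$ on the flow axis and vanishing at the cell radius $r$;
the profile factor is clamped to zero outside that disk. The resultant of
the full profile over the disk is $P_0 \pi r^2 / 2$ (half the plug-flow
value), a closed form the tests verify against quadrature.
`apply_traction()` exposes the pointwise field; its "front region" is the
upstream half of the surface relative to the instantaneous centroid.

Inside the contact simulator the load needs three further decisions, made
after the obvious alternatives failed in testable ways:

* **Direction.** The push acts along the inward surface normal (a
  pressure, as a fluid exerts), not along a fixed $+x$. A fixed-direction
  dead load cannot squeeze the rear of the cell toward the axis; the cell
  then wedges like a cork, with wall reactions growing in proportion to
  the load, and no finite escape pressure exists. The normal-direction
  load feeds material through the waist and restores a finite, mesh-stable
  threshold.
* **Profile attachment.** The parabolic weight is pinned to the material
  surface (evaluated on the reference sphere). Evaluating it at deformed
  coordinates switches the drive off as the squeezed cell spreads outside
  the loaded disk, producing spurious equilibria mid-passage; the upstream
  flow that the load mimics does not switch off.
* **Update protocol.** The loaded selection (rear-facing facets upstream
  of the centroid) and the facet normals are refreshed at the start of
  each load increment, then frozen, so every minimisation works on a
  conservative (dead) nodal force field.

## The contact simulator

The cell is a homogeneous neo-Hookean sphere; the pillar pair is rigid
(the elastomer is about three orders of magnitude stiffer than the cell).
The strain energy density is

$$W = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}\left(\tfrac{J^2-1}{2} - \ln J\right),
\qquad C_{10} = \frac{E}{4(1+\nu)}, \quad D_1 = \frac{6(1-2\nu)}{E},$$

with $\nu = 0.3$ by default. The volumetric function is the
log-regularised form: it agrees with the common quadratic penalty
$(J-1)^2/D_1$ to second order at $J = 1$ (identical bulk modulus) but
diverges as $J \to 0$. That matters here: hard contact at the gap can
compress coarse elements severely, and with a quadratic penalty they
collapse to the inversion cliff and paralyse the solver. Below
$J_0 = 0.05$ the energy is continued by its second-order Taylor expansion
written in terms of $\mathrm{cof}(F)$, so the energy and gradient remain
finite and smooth for any configuration, including transiently inverted
elements; accepted equilibria are checked to satisfy $J > 0$.

**Meshing.** The sphere is meshed by mapping a cube lattice onto the ball
(boundary vertices exactly on the sphere) and splitting each cell into six
tetrahedra along a consistent diagonal. The default resolution (6
divisions per axis, about 1300 linear tetrahedra) is the desk-scale
compromise, chosen after checking that refining to 8 and 10 divisions
leaves the trapped/escaped classification and its scaling properties
intact. Because a coarse inscribed polyhedron under-represents the ball,
nodes are scaled radially so the discrete volume equals the exact sphere
volume.

**Contact.** Frictionless penalty contact acts on surface nodes through
the exact signed distance of the rounded pillar cross-section (the
rhombus inset by the fillet radius, offset back by it). The penalty
stiffness is $100\,E/h$ with $h$ the mean element edge, approximating hard
pressure overclosure; penetration at trapped equilibria is monitored and
stays well below 1 percent of the gap. The fillet radius defaults to 2 µm,
representing the moulded smoothness of real pillars (no published value
exists; the threshold is insensitive to moderate changes).

**Solution scheme.** The load is ramped geometrically (factor-of-two
steps) and the total potential energy is minimised per increment with
L-BFGS, restricted by projection to the subspace that is mirror-symmetric
about the two symmetry planes of the problem. The projection is not only
an economy: it removes the rigid tumbling and drift modes that a
node-attached dead load would otherwise exploit. At full load the state
is re-equilibrated in rounds (refreshing the load selection) until it
stops moving.

**Trapped vs escaped.** Passage is a snap-through: as the pressure
crosses the threshold, the equilibrium jumps from well upstream of the
gap throat to well downstream. The simulator therefore classifies
"escaped" when the centroid passes the throat plane by 0.1 cell radii —
any margin inside the snap band gives the same answer, and pre-snap
equilibria always keep the centroid upstream of the throat. A run that
neither escapes nor converges within budget is treated as trapped, with a
warning.

**Critical pressure.** `find_critical_pressure()` brackets the threshold
by doubling from 1 Pa and bisects to a relative bracket width of 5
percent, reporting the upper (escaping) end. Each trial continues
quasi-statically from the trapped equilibrium at the highest lower
pressure — the protocol of a slowly ramped pump, and the reason results
are deterministic and monotone. Two properties are exact for this model
class and serve as standing self-checks: doubling $E$ doubles $P_c$, and
jointly rescaling cell, gap and pillar dimensions leaves $P_c$ unchanged.

**Validity envelope.** `sweep_critical_pressure()` simulates the grid of
cells and gaps that feeds the regression. Beyond roughly five-fold
squeezes ($a/g \ge 5$) the quasi-static search loses its monotone
ordering in the gap — an internal consistency failure detectable without
reference to any expected fit — so such combinations are recorded as
failed and excluded from regression, as are free-passage combinations
($a \le g$). This envelope also covers the design range of the 25
percent gap rule, whose operating point is $a/g = 4$.

On the default sweep (diameters 10–30 µm, moduli 350 and 650 Pa, gaps
4–10 µm), the acceptance tests compute the model-order comparison: the
quadratic law ranks above the linear and cubic alternatives, and the
freely fitted exponent lies nearer 2 than 1 or 3. The absolute
coefficient of the quasi-static model is larger than the published
calibration — the reference simulations were explicit-dynamics runs whose
transients assist escape — which is why the package's checks rest on
scaling, ordering and self-consistency properties rather than on
reproducing absolute thresholds.

## The carrier-flow solver

`solve_flow()` computes steady incompressible flow through one trapping
unit with stabilised equal-order (P1–P1) finite elements on a graded
tensor-product triangulation. The domain is one array pitch wide: the
side walls pass through the pillar centres, so the visible half-pillars
seal the channel and all flow crosses the central gap. Pillar interiors
are excluded from the discretisation; their stair-cased boundary nodes are
no-slip, with exact grid lines on the gap edges so the throat is
resolved sharply. Velocity is prescribed at the inlet from the flow rate,
the outlet is traction-free, and an optional depth-averaged drag
$12\mu/h^2\,u$ represents the top and bottom channel walls (on by
default). The convective term is available through Picard iteration but
off by default: at gap Reynolds numbers of order one or less the Stokes
approximation is appropriate, and it keeps the documented proportionality
of pressure drop to flow rate exact.

Pressure stabilisation is of Brezzi–Pitkaränta type with the coefficient
$0.05\,h_{max}^2/\mu$ per element, scaled by the longest edge because the
graded mesh is anisotropic where the spacing changes. The constant was
verified against the plane-Poiseuille closed form on a straight channel
(second-order convergence, better than 1 percent at the default
refinement of one tenth of the gap). Discrete mass conservation is exact
in the weak sense, so inlet and outlet fluxes balance to solver
precision. Nodal pressures from equal-order elements carry mesh-scale
noise near the stair-cased tips; `pressure_along_gap()` offers a
moving-average window for smooth profiles, and the unit tests bound the
residual noise relative to the total drop.

Two caveats. First, the flow rate is the rate through *one* trapping
unit: feeding a whole-device syringe rate through a single gap produces
proportionally larger pressure drops than any one unit sees in a parallel
array. Second, the velocity profile across the sharp-edged throat is
slightly flat-topped (orifice-like) rather than fully parabolic; a
best-fit parabola reaches $R^2 \approx 0.94$ at the default settings and
this does not sharpen with refinement. The often-quoted "parabolic"
description of gap flow is accurate for developed channels but only
approximate at a sharp constriction, and the package reports what its
model actually produces.

## Synthetic cohorts and design outputs

`generate_cohort()` draws diameters from a normal model with the measured
A549 parameters (mean 17.27 µm, SD 2.91 µm) as defaults; every cell
carries a modulus (default 430 Pa). The generator is untruncated by
default: truncating to the observed 12–28 µm range shifts the mean by
about +0.2 µm and would break agreement with the measured mean.
`generate_cohort_binned()` reproduces the reported population bins (60
percent at 12–17 µm, 23 at 18–19, 13 at 20–22, 5 above 23); as printed
these sum to 101 percent and are renormalised with a warning. What the
generator emulates is the marginal size distribution only — real cohorts
carry size-stiffness correlation, shape irregularity and cell-cycle
structure that the model does not, so passing cohort tests demonstrates
correct sampling and routing logic, not biological fidelity.

`route_cohort()` sends each cell through a strictly decreasing gap
sequence (default 14, 10, 8, 4 µm) and captures it at the first array
where the rule fires; cells never captured are counted as escaped rather
than forced into the last array. The size-fraction rule captures where
`gap <= fraction * diameter` (non-strict, so boundary ties are captures —
a measure-zero choice documented here); the critical-pressure rule
captures where the predicted $P_c$ exceeds the operating pressure. The
observed A549 bin-to-array correspondence is shipped as a fixture table
(`a549_capture_table()`) because no single threshold fraction reproduces
it: the 25 percent rule matches the smaller cells while the largest cells
are captured earlier than it predicts.

`operating_pressure_curves()` evaluates the power-law model for the
packaged six-line tumor-cell panel across gaps. Under a pure power law
the ratio of two cell types' curves is gap-independent
($E_1 a_1^2 / E_2 a_2^2$); absolute differences do widen as gaps shrink,
which is the practically relevant view for choosing a pump pressure and
the one the plotting helper emphasises.

## Known limitations

* The mechanical model is quasi-static: inertial assistance during
  escape is absent, so absolute critical pressures sit above
  explicit-dynamics references; ordering and scaling properties are the
  reliable outputs.
* One-way coupling only: the flow solver supplies a pressure scale to the
  load model; the cell does not perturb the flow, and lubrication films
  between cell and pillar are not modelled.
* Very deep squeezes ($a/g \ge 5$) are outside the validated envelope of
  the escape search.
* The flow model is two-dimensional and depth-averaged; fully 3D effects
  at the gap (corner vortices, out-of-plane profiles) are not resolved.
* Cells are homogeneous spheres; nuclei, membranes and viscoelasticity
  are deliberately folded into one effective modulus.
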