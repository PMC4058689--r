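---
title: "Methods: steady-state FFR computation on parametric coronary trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state FFR computation on parametric coronary trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ffrct` estimates fractional flow reserve (FFR) by steady simulation on an
idealized coronary tree. This vignette is the package's account of the
model: its assumptions, the parameters that matter, the numerical choices,
and what the built-in geometry emulator does and does not represent.

## The physiological model

FFR is defined under maximal hyperemia as the ratio of mean pressure distal
to a lesion over the pressure proximal to it. The package computes it in
five stages.

**1. Geometry.** The vessel of interest is a left anterior descending (LAD)
artery reduced to arclength-parameterized axisymmetric segments: a main
trunk with a piecewise-linear sampled diameter profile and straight uniform
side branches. The default emulator is a 100 mm trunk tapering linearly
from 3.5 mm to 2.0 mm (so the trunk is at least 2 mm everywhere) with seven
branches of 2.0 down to 1.0 mm — all at least 1 mm — attached at
{10, 30, 42, 54, 66, 78, 90} mm. Named lesion stations A–D sit between
successive branches at {20, 36, 60, 84} mm. Two constraints drove the
attachment spacing: stenotic extents must never straddle a junction (the
narrowing law and the lumped expansion loss are defined on a junction-free
span), and the longest lesion studied (16 mm) must fit between the first
two branches; the 20 mm first gap accommodates it with margin. The actual
anatomy these defaults emulate is not published at this level of detail;
they are documented stand-ins satisfying the printed constraints, and every
value is overridable through `lad_config()`.

**2. Stenosis.** A lesion is `d(s) = d_normal(s) (1 − ds·w(s))` over an
extent of the stated length, where the window `w` rises from 0 at the ends
to 1 at the throat, so the throat diameter is exactly `(1 − ds)` times the
local normal diameter. The default window is a raised cosine; for lesions
longer than 4 mm the central 20% is clipped at `w = 1` so severity does not
depend on length. Cross-sections are circular (concentric disease); a
trapezoid window is available.

**3. Baseline flow split and outlet calibration.** Healthy-tree outlet
flows follow the generalized Murray's law `Q_i ∝ d_i^k`. The classical
exponent is 3; the default is `k = 7/3`, the value commonly fitted to
epicardial coronary branching, and it is exposed in the configuration
because the exact exponent for any given tree is an empirical quantity.
Each outlet then closes with an affine resistance law `P_i = R_i Q_i +
P_{0,i}`. The pair `(R_i, P_{0,i})` comes from two steady solves of the
*healthy* tree with Murray-prescribed flows — a systolic state (90 mmHg,
80 mL/min) and a diastolic state (55 mmHg, 55 mL/min), chosen to bracket
the resting means (69.54 mmHg, 66.75 mL/min) — followed by an exact
two-point fit. Two consequences deserve emphasis:

* `P_0` is treated as an unconstrained affine closure parameter. With the
  default states the fit gives `P_0 ≈ −22 mmHg` at every outlet. A negative
  back pressure has no literal physiological reading; it is the intercept
  of a line through two operating points, and the model never evaluates the
  closure far outside the calibrated flow range. Constraining `P_0 ≥ 0`
  would make the default two-point calibration infeasible. The fit is
  rejected only when `R ≤ 0` or `P_0` reaches the calibration pressures
  (genuinely inconsistent states). A single-point mode with `P_0` fixed
  (zero or a venous pressure) is provided as the alternative closure.
* The calibrated boundary conditions are a property of the downstream bed,
  not of the epicardial lesion, so they are applied unchanged to stenosed
  trees.

**4. Hyperemia.** Maximal vasodilation is a uniform scaling of every
`R_i` by the hyperemia factor 0.21 (dimensionless, in the measured
physiological range), with the hyperemic inlet total pressure 69.87 mmHg.
The hyperemic flow is emergent, not prescribed: with the default
calibration the healthy tree carries roughly 4.4 times its resting flow,
at the upper end of normal coronary flow reserve. Because every lesion
pressure drop grows at least linearly (and its loss term quadratically)
with flow, this calibration places the model in a regime where severity
bites early; see "Limitations".

**5. Coupled solve and FFR.** Segment spans contribute
`ΔP(Q) = a_v Q + a_t Q|Q|`; junction mass balance closes the system. The
solver holds outlet pressures fixed, solves the junction pressures by
damped Newton (closed-form law inversion per edge, analytic Jacobian), and
relaxes each outlet toward its closure. The relaxation evaluates the flow
term implicitly through the outlet's own sensitivity:

    P_i ← P_i + ω (R_i Q_i + P_{0,i} − P_i) / (1 + ω R_i |dQ_i/dP_i|)

The denominator matters. Coronary outlet resistances exceed the epicardial
path resistance by two to three orders of magnitude, so the *explicit*
damped update amplifies any closure error by `ω R_i |dQ_i/dP_i| ≫ 1` and
diverges for every practical `ω`; evaluating the flow at the new state
(the sensitivity is extracted from the converged Newton Jacobian) keeps
the same fixed point and is stable for all `ω ∈ (0, 1]`. Convergence is
declared when the closure residual `|R_i Q_i + P_{0,i} − P_i|` falls below
`tol_pa` at every outlet, which is the invariant the solution must satisfy;
the converged state is independent of `ω` to well within solver tolerance.
The inlet honors *total* pressure by subtracting the dynamic head
`½ρv²` of the current inflow (≈ 0.9 mmHg at hyperemic flow); the
correction applies to forward flow and a negative inlet flow is flagged as
a boundary-condition inconsistency rather than corrected.

`FFR_CT = P_d / P_a` is sampled on the trunk 5 mm proximal and 10 mm
distal of the extent. Offsets are configurable because wire placement is a
clinical convention, not a property of the lesion; sampling stations clip
at the nearest junction so a reading never mixes pressures across a branch
point.

## The stenosis loss law and its PDE cross-check

The lumped lesion model adds `a_t = Kt (ρ/2)(1/A_throat − 1/A_normal)²`
(a viscous + expansion-loss decomposition in the Young–Tsai family) to the
integrated Poiseuille coefficient of the narrowed profile, with
`Kt = 1.52` by default. Because such empirical coefficients were fitted to
particular lesion shapes, the package carries its own referee: an
axisymmetric steady incompressible Navier–Stokes solver.

The PDE solver works in streamfunction–vorticity form on a radially mapped
grid (`η = r/R(z)`, uniform nodes, full metric terms, spline-smoothed
wall). This formulation was chosen over a pressure–velocity (SIMPLE-type)
scheme because the cross-sectional flux equals `2π(ψ_wall − ψ_axis)`
*identically* — discrete mass conservation by construction — and because
two scalar fields with no pressure–velocity coupling make a far smaller
and more robust core (implemented in C++ via Rcpp). Numerical choices:
first-order upwind convection with a deferred-correction central scheme
(weight 0.9); SOR for the streamfunction (factor 1.6, 4 sweeps per outer
iteration); wall vorticity from a second-order two-point (Jensen) closure
in the mapped metric, underrelaxed by 0.3; vorticity underrelaxation 0.7;
convergence at scaled residuals below 1e-6 with a 20 000-iteration cap,
non-convergence always flagged. Axial pressure is recovered by
integrating the axial momentum equation along the axis, where
`μ∇²u_z = −2μ ∂ω/∂r`; at developed inlet/outlet sections the cross-stream
pressure variation vanishes, so this equals the area-averaged drop. The
domain is padded with straight tube (3 diameters upstream, 10 downstream)
so the outflow boundary does not clip the recirculation bubble; a laminar
Reynolds cap (default 2000 on the throat diameter) guards the modeling
assumption. Verification: a straight tube reproduces the parabolic
profile (centerline/mean = 2 within 1%) and the Poiseuille drop within 2%
with drops grid-converged to under 2% on refinement, and the algebraic law
tracks the PDE drop within 30% (typically 2–12%) for moderate lesions at
throat Reynolds numbers 100–200. Reattachment is detected as the first
downstream sign change of wall shear; the reattachment length is measured
from the throat.

## What the emulator represents — and what it does not

The synthetic tree reproduces the *structural* conditions of the study it
models: diameters, taper, branch count, lesion grids (DS 45–75%, lengths
4–16 mm, four stations), fluid constants, resting/hyperemic anchors, and
the calibration protocol. It does not reproduce: real centerline curvature
and non-circular lumens, surface irregularity of diffuse disease, vessel
compliance or motion, pulsatility (all quantities are time-averaged
steady), non-Newtonian rheology, or the specific unpublished geometry
behind any published FFR value. Passing tests therefore demonstrate
internal correctness (conservation, monotone severity response, calibration
closure, PDE agreement) and reproduction of the *qualitative* clinical
pattern — FFR falls with severity and length, proximal lesions are more
severe, total supply drops while the proximal branch steals flow — not
agreement with any particular patient or animal measurement.

On quantitative transfer: with the default calibration (flow reserve ≈ 4.4)
and `Kt = 1.52`, severe lesions are strongly flow-limiting, so the severity
curve of this model falls considerably faster at high DS than published
image-based CFD curves, which were obtained on different geometry and an
unpublished hyperemic flow state; the package's own PDE solver confirms the
lumped losses, so the difference is a property of the study conditions, not
of the surrogate. Uniform rescaling of all outlet resistances (factors
0.29–1.71) changes the hyperemic flow severalfold and therefore changes
FFR of an intermediate lesion by tens of percent in this model; a reported
near-insensitivity to resistance error is attainable only when estimation
errors largely cancel across outlets, which uniform scaling deliberately
does not do. Both behaviors are computed, not asserted, by the test suite
and the acceptance script.

## Degenerate inputs and tie-breaks

* `ds = 0` or zero lesion length solve the baseline geometry; FFR is then
  evaluated at the same sampling stations and stays near 1.
* Stenotic extents that would contain a junction attachment are rejected
  naming the junction; extents may touch a junction at their endpoints
  (where the window is zero).
* A severity sweep that never crosses the FFR threshold reports the
  attained range instead of extrapolating.
* Identical calibration states (zero flow difference) are a calibration
  error, not a division by zero.
* All sweeps are deterministic given the configuration; every artifact is
  stamped with the configuration hash.

## Problem sizes

The study model solves in fractions of a second (8 junction-free trunk
spans + 7 branches, Newton on 7 junction pressures, ~100 outer
iterations). PDE verification uses 24×160 to 48×384 (radial × axial)
nodes — a few seconds per solve in the compiled core; these sizes sit on
the grid-convergence plateau established by the refinement test.

## Known limitations

* The outlet closure is a two-point affine fit; intramyocardial pressure
  phasicity, autoregulation and microvascular disease are out of scope.
* The expansion-loss coefficient `Kt` is shape-dependent; for lesion
  shapes far from the smooth concentric default, tabulate the law from the
  PDE solver (`tabulate_from_axisym()`) instead of trusting the default.
* The axisymmetric solver covers single tubes; branch junction
  hemodynamics (skewed profiles, junction losses) are represented only
  through the lumped network.
* Location effects depend on the emulator's branch layout; with a
  different layout the ordering A–D persists but the magnitudes shift.
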