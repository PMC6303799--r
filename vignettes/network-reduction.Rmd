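---
title: "Pulse-wave simulation and topology reduction of arterial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-wave simulation and topology reduction of arterial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

One-dimensional (1D) blood-flow models resolve pressure and flow pulse waves
along networks of compliant arterial segments. Detailed networks (tens to
hundreds of arteries) produce realistic waveforms but demand a parameter set
— geometry, wall stiffness, outflow impedances — whose uncertainty grows
with every added segment. `pulsetrim` implements the opposite move:
systematically *removing* segments, replacing the amputated beds with lumped
(zero-dimensional, Windkessel) outlets, until the waveform features a user
cares about would start to degrade beyond a stated threshold. The result is
the smallest network, within a well-defined candidate family, whose error
against the detailed baseline stays below that threshold.

## The 1D model

Each segment is a thin-walled elastic tube. Mass and momentum balance in
the pressure/flow variables $(P, Q)$ read

$$\frac{\partial A}{\partial P}\frac{\partial P}{\partial t}
  + \frac{\partial Q}{\partial x} = 0,
  \qquad
  \frac{\partial Q}{\partial t}
  + \frac{\partial (Q^2/A)}{\partial x}
  = -\frac{A}{\rho}\frac{\partial P}{\partial x} + \frac{f}{\rho},$$

with the friction term $f = -2(\zeta + 2)\mu\pi U$ from a power-law axial
velocity profile of order $\zeta$ (default 9, much flatter than Poiseuille
flow, as appropriate in large arteries). Defaults are
$\rho = 1.06\ \mathrm{g\,cm^{-3}}$ and $\mu = 0.035\ \mathrm{P}$; all
internal computation is CGS, with mmHg/ml/mm conversions at the I/O surface
(1 mmHg = 1333.22 dyn cm$^{-2}$).

The wall closes the system through the tube law
$P = P_\mathrm{dia} + (\beta/A_d)(\sqrt A - \sqrt{A_d})$ with
$\beta = \tfrac{4}{3}\sqrt{\pi}\,E h$, and the stiffness $Eh$ comes from an
empirical wall law linking the diastolic radius to the diastolic pulse-wave
velocity, $c_d^2 = \tfrac{2}{3\rho} [k_1 e^{k_2 r_d} + k_3]$, with separate
systemic and (stiffer) coronary coefficient sets. The two relations are
mutually consistent: $\rho c_d^2 = A_d\,(\partial P/\partial A)|_{A_d}$,
a property the test-suite checks on randomly drawn segments. The printed
form of the tube-law prefactor is ambiguous in parts of the literature; the
$\sqrt{A}$ form used here is the only one consistent with the wall law, which
is why it was adopted.

### Numerics

The equations are advanced with the explicit MacCormack predictor–corrector
scheme (forward-difference predictor, backward-difference corrector,
averaged), which is second-order in smooth regions and a standard choice for
1D haemodynamics. Specific numerical decisions:

* **Grid.** Uniform spacing per segment targeting `dx_target` (default
  0.25 cm, at least 4 intervals per segment). Radius tapers linearly
  between the end radii.
* **Time step.** $\Delta t = \mathrm{CFL}\cdot\min_x \Delta x/(|U| + c)$
  evaluated at each cycle start with CFL 0.9. Because wave speed stiffens as
  pressure rises within a cycle while $\Delta t$ stays fixed, the speed
  estimate is inflated by 25% headroom; the solver aborts if the realized
  Courant number ever exceeds 1.
* **Junctions.** At every connection the solver enforces mass conservation,
  total-pressure continuity $P_1 + \tfrac{\rho}{2}U_1^2 = P_i +
  \tfrac{\rho}{2}U_i^2 + \Delta P_i$, and compatibility of the outgoing
  characteristics, extrapolated first-order along the characteristic from
  the adjacent interior node. The resulting nonlinear system (2 unknowns
  per vessel end plus one per attached Windkessel) is solved by damped
  Newton iteration to a scaled residual of $10^{-11}$; junction mass
  defects are tracked and stay below $10^{-8}\max|Q|$.
* **Stenoses.** The stenotic span is removed from the 1D grid and replaced
  by a two-way junction with the empirical loss
  $\Delta P = K_v Q + K_e Q|Q|$. Coefficients are computed from geometry by
  a Young–Tsai-type rule by default but are stored explicitly in the
  network file so any rule can be overridden bit-exactly.
* **Outlets.** Terminal WK3 and coronary Windkessel ODEs are integrated
  with implicit Euler inside the junction Newton solve. Windkessel models
  couple to the *static* pressure of the vessel face (vessel–vessel
  continuity keeps the dynamic term); this convention makes the
  single-vessel steady state match the series-resistance closed form
  exactly and is applied consistently in the steady solver.
* **Coronary outlet topology.** $R_a \to C_a(\to P_{out}) \to R_m \to
  C_m(\to \gamma_{im} P_{LV}(t)) \to R_{v} \to P_{out}$: the intramyocardial
  compliance is referenced to a scaled left-ventricular pressure, which
  raises outlet impedance during systole. $\gamma_{im}$ defaults to 1.
* **Initial condition and convergence.** $P = P_\mathrm{dia}$, $Q = 0$;
  cycles are repeated until the relative cycle-to-cycle $L_2$ change of
  pressure at all output sites falls below `periodicity_tol`
  (default $10^{-3}$), at most `max_cycles` (default 20). The final cycle
  is resampled to 1000 uniform points, which fixes $N_t$ in the average
  error metrics. The underlying literature does not state grid, step or
  convergence choices; all of these are exposed in `solver_config()`.

## Method 1: algebraic lumping

A steady, linearized network solve provides mean pressures and flows:
segment drops $\Delta\bar P = R_v(\bar A)\bar Q$ with
$R_v = \int 2(\zeta+2)\pi\mu/\bar A^2\,dx$, junction continuity with mean
velocities, and the tube law linking $\bar A$ to $\bar P$. Areas are frozen,
the linear resistive network is solved by nodal analysis, areas are updated
from the new pressures (Picard iteration, relative tolerance $10^{-8}$).
Stenoses enter by Newton linearization — tangent resistance
$K_v + 2K_e|\bar Q|$ *plus* the matching lagged source — so the converged
solution satisfies the exact quadratic loss law rather than a
secant approximation.

Cutting at a face, the distal bed is replaced by a WK3 with

* total resistance $R = (\bar P - P_{out})/\bar Q$ (Ohm's law at the cut),
* proximal resistance $R_1 = Z_c = \rho\bar c/\bar A$ (the characteristic
  impedance of the cut face, which minimizes reflection of incoming waves),
* peripheral resistance $R_2 = R - Z_c$ (an error if non-positive: the
  cut is then too close to the periphery to lump), and
* compliance from summing distal contributions: non-terminal vessels
  contribute their volume compliance
  $C_v = \rho^{-1}\int \bar A/\bar c^2 dx$; terminal vessels contribute the
  equivalent compliance of the vessel+outlet pair,
  $C_t = (C_v R_2 + C_v R_1 + C R_2 + C_v R_v)/(R_2 + R_1 + R_v)$
  (coronary: $C_t = C_v + C_a + C_m$). Contributions add in parallel
  (arterial compliances share a common external reference pressure); the
  combiner is a function argument so an alternative series/parallel rule
  can be swapped in.

Coronary cuts are replaced by coronary Windkessels with the lumped totals
split $R_a : R_m : R_v = 0.32 : 0.52 : 0.16$ and $C_a : C_m = 0.11 : 0.89$
— plausible ratios for this outlet family, deliberately exposed as
configuration because no canonical split is available.

Because resistance is preserved by construction, the reduced network
reproduces the baseline steady inlet pressure to Picard tolerance — a
property the test-suite asserts on every fixture. Mean pressure and flow
(hence cycle-averaged indices like FFR) are therefore insensitive to the
reduction; what degrades is pulsatile shape.

## Method 2: per-site optimization

Method 1 never looks at the baseline's pulsatile solution; Method 2 does.
For each cut face: take the baseline 1D flow $Q(t)$ at the face as the
input of the WK3 ODE $C\,dP_c/dt = Q - (P_c - P_{out})/R_2$,
$P = P_c + R_1 Q$; solve for the pressure; and minimize the average relative
pressure error $\epsilon_{P,avg}$ against the baseline pressure. The total
resistance stays fixed at $(P_{avg}-P_{out})/Q_{avg}$ and the optimized
subset is $(\theta_1, \theta_2) = (R_1/R_2,\ C)$ — resistance ratio and
compliance — a choice adopted here because those two parameters are the
identifiable ones when the total is constrained. A derivative-free
Nelder–Mead simplex on $\log\theta$ (2 smooth parameters, no gradients
needed, positivity for free) runs to a relative objective tolerance of
$10^{-10}$, starting from the Method 1 values ($Z_c$-based $R_1$, lumped
$C$). The ODE is integrated with an exact exponential step for
piecewise-linear flow and marched to periodicity (start-of-cycle drift
below $10^{-8}$, at most 50 cycles) — time-marching rather than a harmonic
solution, to mirror how the 1D solver reaches its periodic state. The
objective is evaluated on the solver's 1000-point output grid.

On the symmetric tree fixture the fitted $R_1$ comes out *below* $Z_c$ and
the distal-site $\epsilon_{P,avg}$ of Method 2 is consistently below
Method 1's — the same ordering and mechanism (systolic overprediction by
matched-impedance outlets) seen in detailed arterial models. Coronary cuts
keep their Method 1 parameters; optimizing the five-element coronary outlet
is out of scope.

## The topology optimizer

The candidate family consists of truncations at segment *distal faces*:
cutting at a face removes every segment whose connection to the inflow
passes through it, and cuts compose. On a tree this is equivalent to
retained sets that are parent-closed and keep all or none of each
junction's outgoing branches — mid-segment cuts are not considered (except
at declared stenosis faces, which split segments in the solver grid
anyway). Candidates are enumerated exhaustively (bounded at $2^{20}$
compositions), deduplicated, ordered by ascending artery count, and walked
first-feasible; `exhaustive = TRUE` evaluates all candidates and certifies
minimality. Ties among equal-size feasible candidates break toward the
lowest achieved error. The whole pipeline is deterministic, so a fixed
configuration reproduces the identical outcome.

Quantities of interest are per-site metrics averaged over sites:
$\epsilon_{P,avg}$, $\epsilon_{Q,avg}$ (normalized by the baseline cycle
maximum to avoid zero crossings), $\epsilon_{P,sys}+\epsilon_{P,dia}$,
$\epsilon_{PP}+\epsilon_{P,aug}$, or $\epsilon_{iFR}$ (two sites, proximal
and distal). The augmentation point is the last zero crossing of the
second derivative — after Savitzky–Golay smoothing (2nd-order polynomial,
7-point window at 1000 samples/cycle) — between the diastolic foot and the
systolic peak; when no crossing exists the metric reports "undefined"
rather than zero. iFR uses the last 30% of the cycle as the wave-free
window; with single-cycle periodic waveforms the single-beat/averaged-beat
distinction vanishes.

## Scenario re-parametrizations

* **Ageing**: $\beta \times 2.5$ on a *declared* list of proximal
  aorta/major branch segments (never inferred from names), $\times 1.5$
  elsewhere; every WK3 outlet total resistance $\times 1.1$ via its $R_2$,
  so the parallel total scales exactly; outlet compliances rescaled so the
  total compliance (outlet + integrated 1D after stiffening) exactly
  halves.
* **Coarctation**: a 1 cm long, 50%-diameter stenosis
  ($A_s/A_0 = 0.25$) at a segment midpoint, coefficients from the
  geometric rule.
* **Inflow states**: the ejection lobe of the inflow wave (its contiguous
  positive support) is time-scaled to a new ejection time, embedded in the
  new period $60/\mathrm{HR}$, and renormalized to the new stroke volume.
  The two extreme states HR 56/ET 0.315 s/SV 106 ml and
  HR 120/ET 0.2 s/SV 44 ml are exercised in the tests.
* **Hyperaemia**: coronary outlet resistances divided by $\alpha$
  (defaults 3 for healthy outlets, 1.25 distal of a stenosis), preserving
  internal ratios. All scenario operations are pure: they return modified
  copies.

## What the synthetic fixtures do and do not emulate

`make_fixture()` builds deterministic toy networks: a single aorta-like
vessel (r = 1 cm, l = 10 cm), symmetric binary trees with Murray-consistent
daughter radii ($2^{-1/3}$) and halving lengths, a four-segment ring (the
loop topology of a circle of Willis), and a pressure-driven coronary
bifurcation with one stenosis and coronary outlets. Outlet resistances are
set so the network carries a 93 mmHg mean pressure at the mean of a
half-sine inflow (default HR 60, ET 0.3 s, SV 70 ml — a normal resting
adult); total peripheral compliance is $9\times10^{-4}$ cm$^5$ dyn$^{-1}$
(≈1.2 ml/mmHg, normal total arterial compliance), giving a physiological
$R_2 C$ diastolic decay of roughly 1.2 s and 120/70-ish waveforms. The toy
coronary uses 4.5% of a 90 ml/s cardiac output distributed by Murray's law
and a total coronary compliance of $3.6\times10^{-5}$ cm$^5$ dyn$^{-1}$.

These fixtures exercise every code path — junctions, loops, stenosis
losses, both outlet families, both reduction methods, the optimizer — at
realistic parameter magnitudes. They are *not* anatomically detailed: no
taper heterogeneity, no asymmetric branching patterns, no measured
waveforms. Passing tests therefore demonstrate correctness of the
numerics and the reduction algebra, and the right *direction and rough
magnitude* of method differences; they do not reproduce any particular
subject's waveforms. Applying the framework to a full-body arterial tree
(dozens of named systemic arteries) requires that network's segment table
and boundary parameters as user-supplied data in the documented JSON
schema.

## Problem sizes and known limitations

The shipped tests and the acceptance script run single vessels (40–160
grid nodes, 1–20 cycles), 7-segment trees and the 3-segment coronary toy;
exhaustive topology optimization evaluates the 5-candidate family of the
7-segment tree. These sizes were chosen to make every check run from a cold
start in seconds while still exercising multi-junction wave interaction.

Limitations: elastic walls only (no viscoelasticity); no venous return or
closed-loop heart coupling (the left-ventricular pressure driving coronary
outlets is consumed as an input time series, with a synthetic generator
provided); prescribed-pressure inflow is supported by the pulsatile and
steady solvers but the steady solve of such networks treats the mean inlet
pressure as a Dirichlet value; one stenosis per segment; the candidate
family excludes mid-segment cuts, so an optimal network in a richer family
could in principle be smaller.
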