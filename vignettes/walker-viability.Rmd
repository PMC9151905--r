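---
title: "Viability, speed regulation, and task switching in the simplest dynamic walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viability, speed regulation, and task switching in the simplest dynamic walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
numerical procedures behind each exported operation, the design choices that
were genuinely open, and the known limitations. Nothing stated here as an
empirical result goes beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The model

The walker is the simplest actuated biped with definite swing-leg dynamics: a
point mass at the hip, two straight massless legs of unit length with
infinitesimal point feet, walking on level ground. All quantities are
dimensionless (lengths by leg length $l$, time by $\sqrt{l/g}$, impulses by
$m\sqrt{gl}$). During single support the stance leg is an inverted pendulum
and the swing leg swings passively:

$$\ddot\theta = \sin\theta, \qquad
  \ddot\phi = \sin\theta + (\dot\theta^2 - \cos\theta)\sin\phi,$$

with $\theta$ the stance angle from vertical and $\phi$ the inter-leg angle.
A step ends at heel strike, the root of $\phi - 2\theta = 0$ at which

$$\theta^- \le 0,\quad \dot\theta^- \le 0,\quad \phi^- = 2\theta^-,\quad
  \dot\phi^- \ge 2\dot\theta^-$$

all hold; the spurious mid-swing crossing of the same surface (the classic
foot-scuffing configuration of point-foot walkers, at which the rate
condition fails) is skipped. Just before heel strike an impulsive push-off
$P \ge 0$ acts along the trailing leg; across the impact

$$\theta^+ = -\theta^-, \qquad
  \dot\theta^+ = \dot\theta^-\cos 2\theta^- + P\sin 2\theta^-,$$

and the swing coordinates reset to $\phi^+ = 2\theta^+$,
$\dot\phi^+ = (1-\cos 2\theta^-)\,\dot\theta^+$. The step-to-step dynamics
are the Poincaré map $F(x;P)$ on the post-heel-strike section
$x = (\theta^+,\dot\theta^+)$.

Viability requires: a non-negative stance-foot ground reaction force, whose
minimum over a stance occurs at one of the endpoints, giving the two checks
$\cos\theta^+ - (\dot\theta^+)^2 \ge 0$ and
$\cos\theta^- - (\dot\theta^-)^2 \ge 0$ (the endpoint-minimality is itself
verified numerically in the test suite); and actuation limits
$P_{\min} \le P \le P_{\max}$ with
$P_{\max} = \dot\theta^-\tan 2\theta^-$ for $-\pi/4 < \theta^- \le 0$
(unbounded for steeper angles, where instead
$P_{\min} = -\dot\theta^-\cot 2\theta^-$ keeps the stance foot lifting off).

The convention set (stance/swing equations, impact map, swing reset) was
validated against an independent `deSolve` integration and against the known
short-period passive gait on a shallow slope, which maps onto itself to five
decimals under this implementation.

## Coordinates and grids

In original coordinates the set of states that achieve any heel strike at
all is a thin wedge between the slow boundary
$\Omega_{\text{low}}(\theta^+) = -\sqrt{2(1-\cos\theta^+)}$ (below it, in
magnitude, the stance leg never passes vertical) and the fast boundary
$\Omega_{\text{high}}$ (beyond it the walker falls forward before a
legitimate strike; located per stance angle by bisection on the stance
outcome, tolerance $10^{-8}$). All grids therefore live in scaled
coordinates, where the rate is measured as a fraction of the local wedge
height: 0 on the slow boundary, $-1$ on the fast one. Analyses cover
$\theta^+ \in (0, 0.85]$, the range of human stance angles; in practice all
regions end near $\theta^+ \approx 0.841$ where the start-of-stance
ground-reaction locus crosses the slow boundary
($\cos\theta = 2(1-\cos\theta)$) and the wedge ceases to be viable.

The working grid is $850 \times 201$ (columns $\times$ scaled-rate rows);
the reference resolution for the headline figures in the literature is
$42500 \times 1002$. The package computes areas always in original
coordinates: per column, band extents (with half-grid-cell midpoint edges)
are converted by the local wedge height and integrated across stance angle
by the composite Simpson rule (a 3/8 panel completes even sample counts, so
cubic exactness is kept).

Stance integration uses an adaptive Dormand–Prince 5(4) scheme with
relative/absolute tolerances $10^{-10}/10^{-12}$ and event localisation by
interval halving to $10^{-12}$ in time; stance energy
$\tfrac12\dot\theta^2+\cos\theta$ is conserved to $\sim 10^{-12}$ along
integrated stances. The same adaptive integrator is used inside the basin
sweeps (rather than a fixed-step scheme): it is both faster and more
accurate at these tolerances, and the sweeps are spot-checked against the
single-step reference path in the tests.

## The viability kernel

The 1-step viable region $V_1$ is classified per grid point by one stance
integration plus the two ground-reaction checks; the pre-impact state, step
time, step speed, and the inclusion image of every point are cached, since
every later stage reuses them (one stance integration per grid point, ever).

Over all admissible push-offs the reachable next states from $x$ form a
vertical segment at $\theta_{\text{next}} = -\theta^-$ with rate interval
$[\dot\theta^-/\cos 2\theta^-,\ \dot\theta^-\cos 2\theta^-]$ for shallow
pre-impact angles and $(-\infty, 0]$ for steep ones (the minimal admissible
push-off already brings the post-impact rate to zero there). The kernel
iteration repeatedly removes grid points whose segment fails to meet the
current iterate, where each iterate is represented by per-column
shape-preserving (Fritsch–Carlson) envelope curves fitted through the
non-viable grid points tightly enveloping the estimate; the intersection
test is closed-interval overlap with half-a-grid-cell tolerance. Landings
beyond the $\theta^+$ cap count as leaving the analysed window. Convergence
is a pass with zero removals. The iterates are nested by construction and
their areas are recorded.

Two open details were resolved as follows. Boundary-touching points count as
inside (closed-set convention). Columns with multiple membership runs use
the largest run for envelope fitting; in practice the kernel is a single
band per column.

The unreachable subset is computed from the same cached segments: per
column, the covered set is the band between the lower and upper envelopes of
the segments binned there (segment endpoints vary continuously with the
source state, so their union has no interior gaps); kernel points outside
the band are unreachable. Windowed binning was deliberately not used: it
over-covers the thin image set near the origin, where the image segments
shrink to points, and biases the unreachable fraction low. Isolated
few-cell components are grid noise from the finite sampling of the image
set; the component count that matters is over components holding at least
1% of the member cells (two are expected: one hugging the right edge beyond
the largest attainable landing angle, one along the slow side).

The upper cover envelope is the image of the kernel under zero push-off and
is expected to belong to a critical curve of the non-invertible step map:
preimage counts on its two sides differ by two. Counting preimages by Newton
iteration fails exactly where it matters (the map folds at the critical
curve and the Jacobian degenerates), so the package instead traces the level
curve $\{\theta_{\text{next}} = \text{const}\}$ row by row through the
kernel and counts transversal crossings of the passive landing rate along
it; the local fold value is taken from the trace itself, because the binned
cover envelope carries half-a-column slop, far coarser than the fold.

## Gait families and bifurcations

Period-1 gaits are fixed points of $F(\cdot\,;P)$, found by damped Newton
iteration with central finite-difference Jacobians (step $10^{-6}$) on the
raw map (actuation limits are verified at the solution, not enforced along
Newton iterates). The long- and short-period families are separated by step
time and continued in $P$ with a secant predictor, step $2\times10^{-3}$,
outward from a seed at $P=0.05$; the downward sweep refines its step to
$2.5\times10^{-4}$ near $P=0$ where both families collapse into the origin.
The residual tolerance is $10^{-10}$ with a stall guard an order of
magnitude above it: the residual floor is set by the stance integrator's
tolerance, and demanding more is noise-chasing.

Eigenvalues of the $2\times 2$ finite-difference Jacobian are recorded along
the branch; a real eigenvalue crossing $-1$ (period doubling) or $+1$ (the
transcritical exchange where the two families cross) is bracketed between
continuation points and refined by bisection to $10^{-6}$ in $P$. Steady
speed along the branch is inverted for a target speed by monotone
interpolation plus exact root refinement on the fixed-point speed.

## Step-to-step speed regulation

The regulator minimises the next-step quadratic cost
$(V_{k+1}(x_k;P) - V^*)^2$ over $P \ge 0$ and clips the minimiser to the
actuation limits. Because the next step's speed depends on the current
push-off only through the post-impact state, each cost evaluation is one
heel-strike map plus one stance integration. The cost is finite only on the
window of push-offs whose landing rate lies inside the next column's wedge
(stuck above the slow boundary, falling beyond the fast one), so the scan
is anchored at the slow-boundary crossing and densely resolves the window
(101 points) before golden-section refinement; among equal minimisers the
smallest push-off is taken (left-to-right scan). Where the upper actuation
limit is unbounded the search is capped at a configurable impulse (default
2.0), far beyond any optimum relevant below the transcritical speed range.

An unsaturated minimiser either attains the target exactly (cost $\approx
0$) or sits at a stationary point of the speed in the impulse — the two
branches of the goal-equivalent target-speed manifold, which
`build_target_speed_manifold()` constructs per stance-angle column by root
finding on $V = V^*$ with the speed-extremum branch where the target is
unattainable.

Basin sweeps use the same optimisation over an interpolated speed table
built from the kernel's cached stance results (bilinear in the scaled grid),
so a regulated sweep costs one stance integration per realised step; the
applied impulses agree with the direct optimiser wherever the cost valley is
sharp, and anywhere in the valley they achieve equivalent cost (asserted in
the tests).

## Basins of attraction

Basins are estimated by simulating every kernel grid point (optionally
strided) for 50 open-loop or 25 regulated steps; a trajectory that violates
any viability constraint at any step is not part of the basin, and
membership additionally requires the terminal state within a tolerance of
the attractor in scaled coordinates. The tolerance is 0.01: measured
membership sits on a robust plateau for tolerances in $[0.005, 0.02]$
(halving it moves areas by well under 0.2 area points), while much tighter
values collide with the slowest study gait's convergence rate (eigenvalue
0.95 at $P^*=0.001$: fifty steps contract offsets only to $\sim0.09\times$).
Trajectories within $10^{-6}$ of the attractor exit early as members.

Level-curve basin boundary prediction runs in an empirical mode: the
constants of the $\{\theta^- = \text{const}\}$ edges are fitted to the
simulated basin's pre-impact-angle range (trimmed quantiles), the predicted
basin is the kernel slab between them, and the defining property of the
fitted curves is verified by sampling them through the state space. For
slow targets the prediction is declined: there the basin structure is
shaped by the actuation limits, not by level curves.

## Task switching

A switching policy bundles an ordered set of target speeds, their
precomputed basins on one subgrid, and the final task target. Target
selection returns the final target whenever the state is in its basin, and
otherwise the containing basin whose index is nearest the final one (ties
resolved deterministically toward the lower index) — the simplest
progress-making rule, isolated behind `select_target()` so it can be
replaced. Selection is re-evaluated every step. Recovery episodes step with
the same table regulator as the basin sweeps, so each episode step from
inside a basin is the first step of a trajectory the basin estimate already
certified viable; as a consequence no episode from a covered state can
violate a constraint. Membership is resolved at cell resolution; when a
mid-episode state falls into a quantisation hole of the cover, the
controller keeps its current regulator rather than aborting. An episode
succeeds when the state is on the final target-speed manifold (next-step
speed within $10^{-6}$ of the target) inside the final basin.

## Problem sizes

The package's own study conditions are: kernel grid $850\times201$; basin
start strides of 2 (headline basins) to 10 (parameter sweeps) on that grid;
continuation step $2\times10^{-3}$ with $15$-point basin families for
coverage sweeps; a $425\times1001$ rate-refined kernel for the
boundary-merge diagnostic, whose half-cell criterion is rate-resolution
bound. These sizes keep a full analysis in minutes on one core; all
headline quantities are also well converged under 2× grid refinement
(asserted in the tests) except where noted below.

## Known limitations

- **Speed-regulated basin extents.** With the regulator implemented
  literally as the clipped global one-step argmin, the speed-regulated
  walker recovers far more of the kernel than the reference analysis this
  package sets out to reproduce: from almost any fast state there exists an
  admissible push-off landing exactly on the target-speed manifold in one
  step (the attainable speed window per landing column reaches down to
  nearly zero speed), and the slide along the manifold then contracts at
  $\sim0.38$ per step. The basin *boundary structure* matches the reference
  description — the slow flank is the stable set of the short-period saddle,
  and a saturated slow trap (the closed-loop gait of the
  maximally-pushing dynamics) forms the watershed — but the simulated
  regulated-basin areas are several-fold larger, and correspondingly the
  basin-size maximum over target speeds and the five-basin union differ.
  Two restricted optimiser readings (searching only the feasible branch
  connected to the minimal push-off; anchoring the search to the previously
  applied impulse) were implemented and measured, and neither reproduces the
  reference areas either — the first destroys the nominal gaits themselves,
  the second flattens the growth with target speed. The literal reading is
  the default; the anchored variant remains available via
  `estimate_basin(optimizer = "anchored")`. Open-loop basins, the kernel,
  the unreachable subset, and all bifurcation quantities are unaffected.
- **Upward task recovery.** With the larger regulated basins, a recovery
  episode from a slow state can settle on an intermediate gait whose basin
  nowhere meets the final target's; such episodes remain viable forever but
  never complete the final task. Downward recoveries (fast disturbances)
  complete in a few steps.
- **Boundary merge abscissa.** The stance angle at which the kernel's lower
  boundary merges with the fast heel-strike curve is defined through a
  half-grid-cell criterion and is therefore rate-resolution dependent; the
  estimate climbs with refinement (0.278 at 201 rows to 0.324 at 1001 rows)
  and remains below the reference value at all desk-scale resolutions. The
  gap between the two curves decays below $5\times10^{-4}$ scaled units
  already near $\theta^+\approx0.34$, so the merge point is intrinsically
  soft.
- **No stance-phase actuation, slopes, lateral dynamics, or motor noise**:
  the model is the 2-D deterministic point-foot walker with impulsive
  push-off as its only input.
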