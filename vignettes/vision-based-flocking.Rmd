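---
title: "Vision-based flocking: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vision-based flocking: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`visionflock` simulates self-propelled disk (2D) or sphere (3D) agents
whose only social input is a **binary visual projection field**: the
indicator function $V(\varphi)$ (or $V(\varphi,\theta)$) of the retina
directions occluded by the bodies of other agents.  No agent knows the
positions, distances, headings or even the number of its neighbors; it
reacts to the occupied angular area of its retina and to the edges of
that occupied region.

Each agent carries a signed speed $v$ along its heading $\psi$ and
relaxes toward a preferred speed: $\dot v \supset \gamma(v_0 - v)$.  The
visual response adds, for the speed and heading respectively,

$$\dot v = \gamma(v_0 - v) + \alpha_0\!\left(-\!\int \cos\varphi\,
V(\varphi)\,d\varphi + \alpha_1 \sum_{e}\cos\varphi_e\right), \qquad
\dot\psi = \beta_0\!\left(-\!\int \sin\varphi\, V(\varphi)\,d\varphi +
\beta_1 \sum_{e}\sin\varphi_e\right),$$

where the sums run over the edges $\varphi_e$ of the occupied retina.
The area terms are repulsive (a large body ahead brakes the agent and
turns it away), the edge terms attractive (edges far from the heading
axis pull strongly through the sine/cosine weights).  Their balance
creates short-range repulsion, long-range attraction, and a front-back
equilibrium distance $d^\*$ solving $BL/(2d^\*) = \sin(\arctan\alpha_1)$,
which tends to $BL/(2\alpha_1)$ in the far field.  Temporal-derivative
(optical-flow) coefficients `alpha2`, `beta2` exist as stored hooks but
the implemented dynamics are purely instantaneous; both default to 0.

The retina coordinate $\varphi \in (-\pi,\pi]$ is measured from the
heading, positive to the left (counter-clockwise), so a positive
$\dot\psi$ is a left turn and the sine-weighted edge term is attractive.
Angles are radians, lengths are body lengths (BL, the agent diameter),
and time is measured in units of $BL/v_0$; the defaults $BL = v_0 =
\gamma = 1$ fix these natural units but remain configurable.

### Exact 2D retina geometry

A neighbor at center distance $d$ subtends a half-width
$\arcsin(\min(1, BL/2d))$ about its bearing; overlapping bodies
($d < BL$) are clamped to a half-plane ($\pi/2$), since the model has no
hard-core exclusion.  Occlusion in a binary field is plain set union, so
the field is a union of circular arcs (`arcset`), stored split at the
$\pm\pi$ cut.  All four functionals are evaluated in closed form; no 2D
retina discretization exists anywhere in the package, and the test suite
checks the analytic values against a brute-force rasterized retina with
$2\times10^5$ bins.

The squared retinal derivative of a binary field, $(\partial_\varphi
V)^2$, is ill-defined in the continuum (a squared Dirac delta).  We
interpret the edge functional as a **unit-weight Dirac comb**: every
edge contributes $\mathrm{kernel}(\varphi_e)$ exactly once, independent
of any discretization.  This choice makes $\alpha_1,\beta_1$
dimensionless and is the only normalization consistent with the
far-field equilibrium distance $BL/(2\alpha_1)$ carrying units of
length.  Edges created at exactly $\pm\pi$ by the storage split are
bookkeeping artifacts and are excluded (detected by continuity across
the cut); a fully saturated retina consequently has no edges and zero
area kernels — agents with saturated vision simply coast.

### The cylindrical 3D variant

In 3D each sphere moves with planar velocity $v_\psi e_\psi$ plus an
independent vertical velocity $v_z e_z$; agents never pitch, so the
spherical retina stays anchored to the world vertical and rotates only
with $\psi$.  The retina is discretized into an azimuth–elevation grid
(default $128 \times 64$, midpoint rule, elevation cells symmetric about
the horizon so that the in-plane symmetry — no vertical motion can be
chosen when all agents share one plane — holds exactly on the grid).  A
cell is occupied when its center lies inside some neighbor's spherical
cap.  Only left–right (azimuthal) edges are detected, row by row with
periodic wrap, each contributing its azimuthal kernel once, the row
weighted by $\cos\theta\,\Delta\theta$ for the planar equations and
$\sin\theta\,\Delta\theta$ for the vertical one — the row-wise analogue
of the 2D Dirac comb.  Up–down edges are deliberately ignored.  The
planar speed relaxes with $\gamma$; the vertical velocity equation has
no relaxation term.

Two consequences of this construction are worth keeping in mind.
First, unlike in 2D, the 3D edge attraction decays like $1/d$ (the cap
shrinks along both retina axes), so cohesion acts only at intermediate
range.  Second, a neighbor's cap is invisible once it is smaller than
the grid spacing, which truncates interactions beyond roughly
$d \approx BL\,n_\varphi/(4\pi)$ (about 14 BL at the default grid, ~10
BL at $64\times32$).  Both effects make small 3D groups only marginally
bound (see *Observed behavior* below).

## Numerical scheme

Time stepping is synchronous explicit Euler: all visual fields are
computed from the pre-step states, then $v$ and $\psi$ are updated and
positions advance along the *updated* velocity (the Euler–Cromer
ordering, which avoids spurious energy growth in the undamped vertical
oscillator of the 3D model).  The default step `dt = 0.05` is adequate
for moderate response strengths; the turning equation becomes stiff for
large `beta0` (the crystal regime `beta0 = 10` is run at `dt = 0.002`
here — at coarser steps the minimum pairwise distance is artifactually
driven below one body length), and 3D runs with `lambda0 = 10` use
`dt = 0.01`.  Halving `dt` changes trajectories at first order, as the
tests verify.  The compiled (Rcpp) integrators reproduce the R-level
reference step (`step_swarm`) to near machine precision; trajectories
also record the minimum pairwise distance at *every* integration step so
collision detection is independent of the snapshot stride.

On the spherical retina, the area functionals converge at roughly first
order in the grid spacing (about 1% change when doubling beyond
$256\times128$), but the row-wise edge functionals inherit aliasing
noise from cap boundaries crossing discrete elevation rows and still
fluctuate by a few percent between $256\times128$ and $512\times256$.
The default $128\times64$ grid is therefore adequate for the
qualitative collective phenomenology (the flattening contrast spans
orders of magnitude) but not for high-precision single-derivative
values.

## Initial conditions (what the generator emulates)

`init_swarm` / `init_swarm_3d` draw positions uniformly in a square of
side `ceiling(sqrt(N))` times the equilibrium length $BL/(2\alpha_1)$ —
i.e. near the expected steady-state density — headings uniformly on the
circle, and speeds at $v_0$.  In 3D the vertical coordinate is uniform
in $\pm$ a quarter box side plus a tiny Gaussian jitter: a swarm born
exactly in one plane can never leave it, so purely planar starts would
silently freeze the vertical dynamics.  All draws are seeded;
identical seeds give bitwise-identical swarms and (the dynamics being
deterministic) bitwise-identical trajectories.

These synthetic configurations emulate a dilute, unordered group at
roughly the model's preferred density.  They do not emulate body-shape
variation, sensory noise, behavioral heterogeneity, or boundaries (there
are none — space is unbounded), so passing tests say nothing about
robustness to those features of real animal groups.

## Metrics

`polarization` is the magnitude of the mean unit velocity ($1$ aligned,
$\sim 1/\sqrt N$ disordered); in 3D the full velocity vector is
normalized, so vertical motion degrades planar order.  `nearest_neighbor_stats`,
`extents` and `min_distance_in_window` quantify density, swarm shape and
collision avoidance (a collision is a center distance below one BL).
Steady-state summaries average over the second half of a run by default;
extents over a window are time averages of instantaneous extents (the
alternative — a running maximum — is hostage to single excursions).
`structure_persistence`, the lagged correlation of the pairwise-distance
vector, separates crystal-like states (locked relative positions, values
near 1) from fluid swarms (values near 0); raw nearest-neighbor identity
turnover cannot make this distinction because crystal agents oscillate
by about a body length around their sites, flipping nearest neighbors
without rearranging.  `pair_response_map` tabulates the instantaneous
speed and turning response to a single neighbor over front-back /
left-right placements; its `dv` zero crossing reproduces the two-agent
equilibrium distance, a cross-module consistency the tests enforce.

## Observed behavior at desk scale

The checks shipped with the package run at reduced problem sizes (N up
to 50 in 2D, pairs in 3D, $10^4$–$10^6$ Euler steps); these sizes are
stated here as the package's own choices.

* **Two-agent equilibrium.**  A front-back pair released at 5 BL with
  $\alpha_1 = 0.04$ settles within 2% of the balance distance
  $d^\* \approx 12.51$ BL in $t \approx 1000$.

* **Collective states (2D, N = 50).**  The fluid-swarm and crystal
  parameter sets reproduce their signatures from random initial
  conditions.  The polarized-line state is *dynamically stable* here (a
  line perturbed by ±0.3 rad in heading and ±2 BL in position returns to
  and sustains polarization ≈ 0.96) but is not reached from uniform
  random initial conditions within $t = 3\times10^4$ at this N; the
  corresponding check therefore initializes near the line and verifies
  the state is self-sustaining.  Ordering from disorder at `beta0 =
  0.01` evidently needs far longer horizons (or different initial
  densities) than a desk-scale run affords.

* **3D flattening transition.**  With the printed 3D parameter set
  ($\alpha_0 = 5$, $\beta_0 = 2$, $\lambda_0 = 10$, $\alpha_1 = \beta_1
  = 0.1$), a bound pair perturbed one body length out of the plane stays
  flat (time-averaged vertical extent ≈ 0.6 BL < 1 BL) when $\lambda_1 =
  0.2 > \alpha_1$, and spreads vertically by orders of magnitude (≫ 10
  BL) when $\lambda_1 = 0.05 < \alpha_1$.  Two caveats, both documented
  limitations of this realization rather than tuned-away facts: the
  vertical velocity has no damping term, so in the flattened regime the
  pair oscillates indefinitely with an amplitude set by its initial
  vertical offset (we probe with a one-BL perturbation for that reason);
  and larger 3D groups (N ≥ 5) at these parameters evaporate here —
  strong vertical kicks at close passes, undamped $v_z$, the $1/d$ decay
  of 3D edge attraction and the finite retina resolution conspire
  against desk-scale cohesion, so the flattening contrast is
  demonstrated on pairs (which the original phase diagrams also
  include).

* **Small dense groups** (N = 10, $\alpha_1 = \beta_1 = 0.2$) polarize
  strongly (P ≈ 0.9–0.99 across seeds and several $(\alpha_0,\beta_0)$
  cells), and the crystal regime keeps every center distance above one
  body length after its transient — collision avoidance without any
  dedicated avoidance rule.

## Worked example

```{r example}
library(visionflock)

p <- vf_params(alpha0 = 0.5, beta0 = 0.02, alpha1 = 0.2, beta1 = 0.2,
               dt = 0.05)
sw <- init_swarm(10, p, seed = 1)
tr <- run_swarm(sw, 20000, record_every = 200)
summarize_run(tr)
```

Sweep drivers (`phase_sweep_2d`, `lambda_sweep_3d`) run one seeded
simulation per parameter cell from a YAML/JSON config and emit one
summary row each; failed cells are recorded in an `error` column and do
not abort the sweep.  A thin command-line driver wrapping these
functions ships in `inst/cli/visionflock.R`.

## Known limitations

Binary vision only (no depth, color or contrast attenuation); no
temporal-derivative (optical-flow) response; no noise terms; unbounded
domain without periodic boundaries; the 3D variant is cylindrical only
(no pitch/roll kinematics) and ignores up-down retina edges; explicit
Euler requires regime-dependent step sizes in the stiff corners of
parameter space; and the discretized spherical retina truncates 3D
interactions beyond a grid-dependent range.
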