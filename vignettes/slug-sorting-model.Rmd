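---
title: "A viscoelastic cell-based model of slug cell sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A viscoelastic cell-based model of slug cell sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slugsim)
```

## The model

`slugsim` simulates the migrating-slug stage of *Dictyostelium discoideum*
as `n` discrete, oriented ellipsoidal cells in three dimensions.  Two cell
types, prestalk and prespore, share the same mechanics but may differ in how
strongly and how directedly they generate motive force.  The question the
simulator addresses is which differences suffice to sort the prestalk cells
to the slug's anterior.

### A cell: three standard linear solids around a conserved volume

Each cell is an ellipsoid with body frame $(\mathbf a,\mathbf b,\mathbf c)$
and semi-axes $(a,b,c)$ (rest value 5 um, i.e. a 10 um cell).  Each axis is
a standard linear solid (SLS): a spring $k_i$ in parallel with a Maxwell arm
(spring $\bar k_i$ in series with a dashpot $\mu_i$).  The deformation $u_i$
of axis $i$ under axis force $f_i$ obeys

$$u_i' = \frac{\bar k_i/\mu_i\,(f_i + \lambda - k_i u_i) + df_i/dt}
             {k_i + \bar k_i},$$

and the pressure-like multiplier $\lambda$, shared by the three axes, is
chosen so that the cell volume is conserved.  Because each $u_i'$ is affine
in $\lambda$, the volume-rate condition is a scalar linear equation
(`solvePressure()`).  With the default constants
($k = \bar k = 100\,$g/s$^2$, $\mu = 160\,$g/s) an SLS axis shows an
instantaneous elastic jump $f/(k+\bar k)$, creeps to $f/k$, and has time
constant $\tau = \mu(k+\bar k)/(k\bar k) = 3.2$ s.

Numerically the axis ODE is advanced by an exact exponential update at
frozen force, with $\lambda$ projected each step (a scalar Newton solve) so
that the *discrete* update conserves the product $abc$ to machine precision.
This sidesteps stiffness entirely and makes volume drift attributable only
to the shape-fitting step discussed below.

### Overlap geometry and deformed-shape fitting

Two cells interact through the line of centers $\mathbf v_{ij}$.  Each
cell's support distance $d_i$ (center to surface along $\pm\hat{\mathbf
v}_{ij}$) gives the overlap $d_{0} = \max(0, d_i + d_j - \|\mathbf
v_{ij}\|)$.  An overlapping cell is refitted so its boundary passes through
the midpoint of the overlap segment ($d^{new} = d_i - d_0/2$; when a single
neighbour's boundary has passed the cell center, $\|\mathbf v\| - 0.7 d_j$).
With one neighbour the system is underdetermined and we minimize the sum of
the semi-axes subject to the boundary point and the volume; with two it is
solved exactly; with three or more a bounded nonlinear least squares runs
through all target points.  In the least-squares case volume can genuinely
not be conserved (conflicting targets), so it enters as a mild dimensionless
residual (weight 1) rather than a constraint: fits then lose up to a couple
of percent of volume under heavy crowding, which the exactly-conserving
relaxation neither amplifies nor removes.  This is the only volume leak in
the scheme, and it is bounded by the fit quality, not by integration error.

Semi-axes are clamped to rest $\pm 1$ um per axis.  For the default 5 um
sphere this is the admissible band $[4, 6]$ um; expressing the band relative
to rest keeps the elongated prestalk variant's rest shape
$(6.25, 4, 4)$ um admissible, which a fixed $[4,6]$ box would clamp even
when unstressed.

The single- and double-neighbour fits use damped Newton iterations on the
KKT/constraint systems (constraint tolerance $10^{-9}$, at most 200
iterations, stagnation bail-out after 10 non-improving steps); infeasible or
non-converged cases fall back to the bounded least-squares path, whose
clamped result is the documented "best fit at the bounds".  Coincident cell
centers (below $10^{-9}$ um) are treated as deep overlap along a random
direction.

### Forces

All motion is overdamped: $M(\mathbf p)\,\mathbf p' = \mathbf F(\mathbf p)$.
The force on a cell sums:

* **Motive force.**  A cell pulls on the nearest cell center inside a cone
  of half-angle $\psi$ about its polarization axis $\mathbf a$:
  $F_m = \kappa\,\hat{\mathbf v}_{ij}$ on itself and the opposite on the
  pulled neighbour (its traction).  $\kappa = 0.4$ g um/s$^2$, $\psi =
  30^\circ$ for prestalk; $\kappa = 0.01$, $\psi = 90^\circ$ for prespore.
  Distance ties break to the lowest cell index.  One eligibility condition
  restricts the candidates: a center the cell has already engulfed (center
  distance below the cell's own support radius toward it) cannot serve as a
  pseudopod anchor and is skipped, so a deeply overlapped cell reaches for
  the next center beyond.  Without this, a strong cell pulls one neighbour
  into a nucleus-force standoff whose pair force is exactly central and
  laterally neutral — the grip never releases and no cell ever passes
  another.
* **Adhesion.**  Normal component $\alpha\,\zeta\,\hat{\mathbf v}_{ij}$
  through the sphere-intersection contact area $\zeta$, computed with cells
  enlarged by 1.4 (cells grab before their surfaces touch), constant while
  the enlarged overlap is below $0.1(d_i+d_j)$ and ramped quadratically to
  zero at $0.3(d_i+d_j)$; $\alpha = 0.1$.  The printed closed form for
  $\zeta$ is evaluated with the center distance as its distance argument;
  the algebra then reduces to the standard lens formula (the tangency zero
  and the $9\pi$ value at radii 5 and distance 8 pin this down).
* **Boundary.**  The substrate and slime sheath confine x and z to a 35 um
  channel with a piecewise-linear inward force of stiffness $\rho = 10$
  g/s$^2$, saturating at $r\rho$ outside; y is free.
* **Rheological forces.**  The restoring SLS force of each refitted cell,
  $-(k+\bar k)(s^{new}-s)$ per axis, is projected on the line of centers and
  pushes the neighbour, with the equal-and-opposite reaction; each axis
  contribution is weighted by $|\mathbf e_k \cdot \hat{\mathbf v}_{ij}|$,
  which is invariant to the arbitrary sign of the body axes.  When centers
  come within the 4 um nucleus diameter an exponential nucleus repulsion
  $10(e^{3(1/\|v\|-1/4)}-1)$ is added (capped at its 0.5 um value to avoid
  overflow).
* **Drag matrix.**  $M$ is block-structured with
  $M_{ij} = -\chi_{ij}\mu_{cell} I$ and $M_{ii} = (\chi_{ii}\mu_f + \sum_k
  \chi_{ik}\mu_{cell}) I$, where $\chi_{ij} = \zeta_{ij}/(4\cdot 5^2\pi)$
  normalizes the cell-cell contact area (bare surfaces, not the enlarged
  adhesion radii) by the cell surface and $\chi_{ii} = \max(0,
  1-\sum_j \chi_{ij})$ is the residual fluid contact;
  $\mu_{cell} = 20\mu_f$, $\mu_f = 0.1$ g/s.  Since every block
  is a scalar times $I_3$, the $3n \times 3n$ solve reduces to an
  $n \times n$ solve with three right-hand sides; a ridge of
  $10^{-9}\mu_f$ keeps it positive definite even when interior cells have
  $\chi_{ii} = 0$.

### Orientation control

The chemoattractant biases all cells toward $+y$.  Each cell's stimulus
direction $\mathbf d$ is drawn uniformly from the spherical cap of
half-angle $\gamma$ about $+y$ and the cell rotates its frame about
$\mathbf a \times \mathbf d$ in increments (default $5^\circ$ per time
step) until aligned; anti-parallel configurations flip front to back.
Neither $\gamma$ nor the fluctuation timescale is a measured quantity:

* $\gamma$ defaults to $15^\circ$.  Sorting speed is sensitive to it,
  because lateral force fluctuations are what let a strong cell slip past
  the cell in front instead of pushing it forever head-on.
* $\mathbf d$ is resampled every 1 s of simulated time (1000 steps).
  Resampling every time step makes the noise average out over any
  mechanical timescale — the motive pull becomes effectively deterministic
  and head-on, encounters deadlock, and sorting stalls.  Persistence on the
  second scale (comparable to the SLS time constant) keeps $\gamma$
  meaningful as the noise-magnitude knob.  Both settings are configurable
  (`gamma`, `resampleEvery`).

### Time stepping: the lagged-shape scheme

Shapes and positions evolve by operator splitting.  Over a shape-lag
interval the radii $\mathbf r$ are frozen at $\mathbf r(t_0)$ and positions
follow $M(\mathbf p(t), \mathbf r(t_0))\,\mathbf p'(t) = F(\mathbf p(t),
\mathbf r(t_0))$; at the interval's end the overlaps at the new positions
are turned into instantaneous deformations (the refitting above) and every
cell then relaxes force-free toward its rest sphere for the length of the
interval.  Both cadences default to $dt = 0.001$ s: shapes update every
position step.  The lag interval (`shapeUpdateInterval`) is configurable,
and it acts as a contact-compliance dial rather than a mere numerical
knob: the sustained push a squeezed contact can regenerate per interval is
$\sim (k+\bar k)(1-e^{-\Delta/\tau})\,u$, so long lags ($\Delta \gtrsim
0.05$ s) make contacts effectively rigid at the motive-force scale (the
packing jams and no cell can displace another), while at $\Delta = dt$ a
sustained pull of magnitude $\kappa = 0.4$ can creep through a contact —
the regime in which cells can pass each other, with the exponential
nucleus force as the hard backstop.

Positions integrate with explicit Euler under local error control: within
each $dt$ the step is subdivided so that no cell moves more than 0.1 um per
force evaluation (at most 200 subdivisions).  A fixed explicit step at
$dt = 0.001$ s sits at the stability boundary during overlap-force spikes
(the stiffest force gradients are $\sim 200$ g/s$^2$ against drags of
$\sim 0.1$ g/s for weakly coupled surface cells); the displacement cap
resolves those transients at their natural cost and is a no-op elsewhere.
Fixed-step `"euler"` and midpoint `"rk2"` integrators remain available for
comparison.

One sign convention matters for stability: the projected overlap push of a
deformed cell on a neighbour, $\sum_k f_k |\mathbf e_k \cdot \hat{\mathbf
v}|$, can come out negative when volume-conserving expansions dominate an
oblique contact.  Rheological forces repel by definition, so the pair push
is clamped at zero; without the clamp the spurious attraction cascades in
multi-cell packings and a fully passive lattice implodes.

## What the initial-state generator emulates

`initLattice()` reproduces the study conditions: a rectangular lattice
(3 x 5 x 3 at 10 um pitch for the default 45 cells, 5 x 10 x 5 for the
250-cell option) centered in the channel cross-section with the long axis
along y, uniform positional jitter of $\pm 0.5$ um, all cells starting as
rest spheres polarized along $+y$.  Prestalk placement is one posterior
center cell, the whole posterior layer of nine, or random sites.  The
generator does *not* emulate: developmental history of the mound (cells
start on a crystal, not a relaxed aggregate), cell-size variability,
differentiation or type switching, cAMP wave dynamics, or substrate
traction — so passing tests on these initial states says nothing about
slugs whose sorting depends on those processes.

## Sorting metric and experiments

The relative prestalk position is $(y_0 - y_1)/(y_2 - y_1)$ with $y_0$ the
mean prestalk y, $y_1, y_2$ the slug's y extremes: 0 posterior, 1 anterior.
It is recorded every 1 s of simulated time, and ensembles run seeds
$s, s+1, \dots$ with per-time mean and SD (`runEnsemble()`).

`experimentPreset()` encodes the study grid: a no-differentiation baseline
(both types $\kappa = 0.01$, $\psi = 90$), force-only and cone-only
differentials, the combined default, prespore-stiffness variants (all SLS
constants scaled 2 or 0.5), anisotropic prestalk axes, and the elongated
prestalk rest shape $(6.25, 4, 4)$ um (same volume as the sphere).

## Numerical choices and degenerate inputs

* Fit tolerances: constraint violation $10^{-9}$ (sub-nanometer), maximum
  200 iterations, deterministic start at the current semi-axes.
* Boundary targets are floored at 0.5 um so deep-overlap targets stay
  geometrically meaningful; fitted axes are clamped to rest $\pm 1$ um.
* Degenerate coincident centers get a random overlap direction from the
  run's RNG stream; the zero-direction stimulus cannot occur
  ($\gamma < 90^\circ$).
* The metric is undefined for a y-degenerate (flat) slug and is signalled
  as an error rather than returning a value.
* Determinism: a run is a pure function of (configuration, seed); the
  RNG is R's stream, consumed in a fixed order (lattice jitter, type
  assignment, then per-step direction resampling).

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full 45-cell slug.
The trend-bearing ensembles (baseline and combined) use 5 seeds over 100 s
of simulated time at $dt = 0.001$ s, recording every second, with the
first 10 s discarded as the mechanical settling transient; the
slower-variant ensembles used for the time-to-gain ordering run 40 s.  The
mechanics, geometry and force suites run on two- and three-cell
micro-scenes and single 45-cell states.  These window lengths are chosen
so the whole suite completes in well under half an hour on one core.

## Sorting rate

Under the default parameterization the model reproduces the qualitative
structure of the sorting problem — a flat no-differentiation baseline,
repulsion-limited passing, and a slow net anterior drift of the strong,
directed prestalk cell — but the drift is far slower than the published
curves suggest: over hundreds of simulated seconds the combined
differential gains on the order of 0.1 in relative position rather than
approaching 1.  The bottleneck is geometric: the nearest-in-cone pull is
central, so an engaged pair has no lateral restoring force and exchange
relies entirely on orientation-noise-driven target switching, whose rate
at $\gamma = 15^\circ$ is small.  Larger $\gamma$ (more signal noise)
measurably accelerates sorting, and the directionality cone $\psi$ gates
how often lateral handholds are available; neither parameter is pinned by
data.  The acceptance checks encode the expected magnitude of sorting and
are reported honestly against this implementation.

## Known limitations

* Cells are permanently ellipsoidal; shape changes are restricted to the
  semi-axes band rest $\pm 1$ um, so extreme squeezing is represented by
  interpenetration plus the nucleus backstop rather than by realistic
  shape change.  Pairs of strongly pulled cells do transiently approach
  center distances of 3-4 um.
* Volume conservation is exact in the axis dynamics but only best-effort
  (percent scale) in crowded multi-neighbour refits.
* The slug has no substrate traction, so only differential motion within
  the slug is meaningful, not slug migration.
* The orientation-noise parameters ($\gamma$, resampling interval) are not
  constrained by data; sorting rates (though not the qualitative ordering
  of the experimental conditions) depend on them.
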