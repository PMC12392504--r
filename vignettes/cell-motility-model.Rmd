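---
title: "A phase-field cell on micropatterns: model, inference, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A phase-field cell on micropatterns: model, inference, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellhop)
```

## The model

`cellhop` simulates a single crawling cell confined to an adhesive
micropattern and infers its effective equation of motion from the resulting
trajectories.  The cell is represented by a phase field $\phi(\mathbf r,t)$
that is 1 inside the cell and 0 outside, with the boundary implicitly at
$\phi = 1/2$.  The field evolves by energy relaxation and interface
advection,

$$\partial_t \phi + \mathbf v\cdot\nabla\phi = -\mathcal M\,
\frac{\delta \mathcal F}{\delta \phi},$$

with a free energy $\mathcal F = \mathcal F_\text{CH} + \mathcal F_\text{area}$
combining a Cahn–Hilliard interfacial energy

$$\mathcal F_\text{CH} = \int d\mathbf r\, \gamma\left[\frac{c_0}{\lambda}
\phi^2(1-\phi)^2 + \frac{\lambda}{2}|\nabla\phi|^2\right],
\qquad c_0 = 16,$$

whose line tension is $\gamma$ and interface width is set by $\lambda$, and a
soft incompressibility constraint
$\mathcal F_\text{area} = \kappa\,(1 - A/\pi R_0^2)^2$ with
$A = \int \phi^2\, d\mathbf r$.  The velocity field comes from local force
balance of an overdamped cell,
$\eta\,\mathbf v = (\delta\mathcal F/\delta\phi)\nabla\phi +
\mathbf f_\text{motility}$, where the active force

$$\mathbf f_\text{motility} = \alpha\,P\,\phi^2(1-\phi)^2\,(1-\chi)\,\hat{\mathbf n},
\qquad \hat{\mathbf n} = -\nabla\phi/|\nabla\phi|,$$

pushes the boundary outward where the polarity field $P$ is positive (and
pulls it inward where $P<0$), but only where the cell touches the adhesive
pattern ($\chi = 0$ on the pattern, 1 off it).

The polarity field summarises front/rear chemical asymmetry (Rho-GTPase-like
signalling) in a single scalar.  It gains localized Gaussian "activity
patches" of width $\sigma$ and random amplitude
$\beta \sim \mathcal N(\mu_\beta, \sigma_\beta)$ once every $\tau_f$ at a
contour point $\theta$, and loses polarity three ways: at rate
$\chi\phi/\tau_\chi$ where the cell overhangs non-adhesive substrate, at rate
$(s/s_0)^2 H(s - s_0)\,\phi/\tau_s$ when the perimeter $s$ exceeds a
threshold $s_0$ (membrane-tension-like global inhibition), and by basal decay
$P/\tau$.  Patch locations are drawn with probability
$p(\theta) \propto (1 - \chi(\theta'))\,\max(P(\theta), 0)$, where
$\theta' = \theta + \ell\,\hat{\mathbf n}$ probes whether adhesive substrate
lies a filopodium's reach ahead of the boundary.  These two couplings — local
inhibition off-pattern and substrate-sensing patch placement — are the only
ways the cell senses geometry.

Negative polarity is physical (it contracts the boundary), but sampling
weights must form a distribution, so $P$ is clamped at zero inside
$p(\theta)$ only.  If every weight vanishes (a fully depolarised cell, e.g.
at $t = 0$), the location is drawn uniformly over the contour so the
scheduler cannot deadlock.  The perimeter inhibition is multiplied by $\phi$
to confine it to the cell; "uniform" inhibition in this model means spatially
uniform *within* the cell body.

### Parameters

`model_params()` carries the default cell.  Units are micrometres and
minutes throughout; $\tau_f$ and $\tau_\chi$ are specified in seconds (as is
conventional for these fast processes) and converted internally.  The
defaults are $\gamma = 0.8\,\gamma_0$, $\lambda = 4.8$ µm, $\kappa = 6000$,
$R_0 = 18$ µm, $\eta = 0.67$, $\mathcal M = 0.75$, $\alpha = 1.4$,
$\mu_\beta = 7.5$, $\sigma_\beta = 37.5$, $\sigma = 6.7$ µm,
$s_0 = 2\pi(1.5 R_0)$, $\tau_f = 2.2$ s, $\tau_\chi = 9.6$ s, $\tau_s = 8$
min, $\tau = 4$ min, $\ell = 6$ µm.  The tension scale $\gamma_0$ is
arbitrary; only ratios matter.  Knockouts are expressed in the parameters
themselves: `tau_chi = Inf` removes the substrate coupling, `s0 = Inf` the
perimeter inhibition, `no_filopodia = TRUE` reduces the placement rule to
$p(\theta)\propto P(\theta)$, and `tau_f = Inf` silences patches entirely.

### Micropatterns

`pattern_spec()` builds the standard geometries: the two-state pattern (two
38×38 µm basins joined by a 10×35 µm bridge), the 111×38 µm rectangle, a
fully adhesive plane, and arbitrary unions of simple polygons for composite
designs.  $\chi$ is a logistic function of signed distance to the pattern
boundary with width `w_chi` (default $\lambda/4$; the original description
says only "transitioning smoothly", so the width is a modelling choice and a
config key).  Corner rounding beyond this smoothing is not applied.
`basin_areas()` supplies the area weights used by the occupancy statistic.

## Numerics

Fields live on a uniform grid with spacing `dx` (default 1 µm, about 3–4
cells across the interface; halving `dx` reproduces all qualitative behavior
and refines the 1D front residual by better than 2×).  Time stepping is
explicit Euler with `dt` validated against the most restrictive of three
rates: the diffusive limit of the interfacial Laplacian
($dx^2/4\mathcal M\gamma\lambda$), the relaxation rate of the global
area-constraint mode ($\pi R_0^2 / 8\mathcal M\kappa \approx 0.028$ min),
and the double-well reaction rate.  The default `dt = 0.005` min also keeps
the advective Courant number below ~0.25 at the peak protrusion speeds the
default parameter set produces.  Boundary conditions are zero-flux on a
domain padded at least $2\lambda$ beyond the pattern; the pattern, not the
box, confines the cell.  $\phi$ is never clipped — clipping would silently
break the gradient-flow property — instead overshoot beyond
$[-0.02, 1.02]$ raises a warning.  The unit normal is zeroed where
$|\nabla\phi| < 10^{-6}/dx$; the motility force vanishes there anyway.

Two perimeters appear.  The evolution equation needs $s$ every step, so it
uses the phase-field perimeter functional
$s \approx 6k \int \phi^2(1-\phi)^2\, d\mathbf r$ with $k = 4\sqrt 2/\lambda$
(exact for the equilibrium logistic front; ~6% below the marching-squares
perimeter at `dx = 1`).  Observables use `extract_contour()`, an ordered
$\phi = 1/2$ polyline with outward normals.

A cell is initialized as a logistic disk whose half-level radius is solved
(bisection) so the *discrete* $\int\phi^2$ starts exactly at $\pi R_0^2$;
the naive choice of putting the half-level at $R_0$ would start ~9% low
because the interface is diffuse.  If the $\phi > 1/2$ region ever splits
into more than one component larger than 5% of the target area, the run is
flagged ruptured; ensembles keep such runs but exclude them from inference,
with a logged count.  Runs whose centroid leaves the pattern bounding box by
more than $R_0/2$ are flagged escaped.

### Observed behavior at the default parameters

The default parameter set produces vivid dynamics: polarity at the
front reaches $P \sim 10^2$, local protrusion speeds tens of µm/min, and
centre-of-mass speeds of order 1 µm/min.  Three consequences are worth
knowing before quantitative use, and are exercised by the acceptance tests:
the cell's area fluctuates by ~2–4% around target during strong protrusion
events (the area-constraint stiffness admits excursions at this forcing);
the boundary transiently overhangs the non-adhesive region because the
off-pattern inhibition (an amplitude-independent rate) needs minutes to
neutralise such large $P$; and most long runs shed a transient fragment at
some point, triggering the rupture flag.  All three soften together if the
patch input is scaled down, which also slows hopping; we keep the default parameter
set as given rather than introduce a hidden rescaling.  In 12-hour
two-state runs the default cell completes at least one basin-to-basin hop in
a majority of seeds, with singly-polarized fronts and tubular bridge
crossings; mid-bridge statistics at this reduced ensemble scale are
dominated by aborted crossings, so the negative-friction signature of the
bridge is not resolved there.

## Inference of F(x, v)

The cell's centre-of-mass dynamics is summarised by the underdamped
stochastic equation $\dot v = F(x,v) + \sigma(x,v)\,\eta(t)$, and the
deterministic part is estimated as the binned conditional mean acceleration
$F(x,v) = \langle \dot v\,|\,x,v\rangle$.  `finite_difference_kinematics()`
downsamples $x(t)$ to `dt_sample` (default 10 min, matching the usual
snapshot cadence), forms $v_k = (x_{k+1}-x_k)/\Delta t$ and
$a_k = (v_{k+1}-v_k)/\Delta t$, and conditions $a_k$ on $(x_k, v_k)$ — the
plain Euler reading; the pairing convention is centralised so it can be
changed.  `estimate_drift_field()` bins samples (36 x-bins over the data
range, 30 v-bins over the central 98% of velocities, `min_count = 20` by
default) with no smoothing; masked bins are never interpolated.

An important statistical caveat, verified in the test suite: when
observations are *coarser* than the generative dynamics, the
finite-difference conditional mean estimates the coarse-grained transition
drift, not the instantaneous one.  For an Ornstein–Uhlenbeck velocity with
friction $\xi$ observed at interval $\Delta t$, the fitted slope is
$(\rho-1)/\Delta t$ with
$\rho = (1-e^{-\xi\Delta t})^2 / [2(\xi\Delta t - 1 + e^{-\xi\Delta t})]$ —
about $-2\xi/3$ even as $\xi\Delta t \to 0$, and $-0.067$ min$^{-1}$ at
$\xi = 0.2$, $\Delta t = 10$.  No pairing convention repairs this (the
midpoint pairing gives 0).  The estimator is therefore validated on fixtures
whose generative step *equals* the observation cadence, where the one-step
conditional drift is exactly $F^*\Delta t$; the bias formula itself is
pinned by a dedicated test so the limitation stays visible.  Cell-simulation
inference shares the same caveat: inferred drifts are `dt_sample`-scale
effective dynamics.

`integrate_streamlines()` iterates $x \leftarrow x + v\,dt$,
$v \leftarrow v + F\,dt$ ($dt = 0.1$ min) from a seed grid, terminating
where both $|v|$ and $|F|$ drop below 5% of their RMS scales, stopping at
the edge of the populated region, or flagging a cycling candidate after
$10^5$ steps.  `classify_phase_portrait()` labels the portrait:
*limit cycle* if at least a quarter of streamlines are non-terminating with
recurrent, winding orbits; *bistable* for exactly two dominant terminal
clusters at $v\approx 0$ separated in $x$ by more than `x_sep` (pass the
bridge half-length for the two-state geometry); *stationary* for terminal
points spread widely along $v = 0$; *other* otherwise (e.g. one point
attractor).  Terminal points are clustered by single linkage at one bin
diagonal; separatrix points are midpoints between adjacent seeds flowing to
different groups.  `bootstrap_inference()` resamples whole trajectories with
replacement and repeats the pipeline with bin edges held fixed, reporting
label frequencies and terminal-point scatter — single portraits from finite
data should not be over-read.

## Synthetic fixtures

`simulate_sde()` generates trajectories with analytically known drift —
Ornstein–Uhlenbeck ($F^* = -\xi v$, stationary), van der Pol
($F^* = \mu(1-x^2)v - x$, limit cycle), and a damped double well
($F^* = -4kx(x^2-x_0^2) - \xi v$, bistable) — so the entire inference stack
is testable with no simulator in the loop.  The three models are the
classifier's acceptance gate.  OU defaults ($\xi = 0.2$ min$^{-1}$, noise
0.6 µm min$^{-3/2}$) put $x$ and $v$ on the scales of the cell problem so
inference defaults transfer.

## Observables

`friction_cut()` averages $F$ over bins near $x = 0$ and fits the
small-velocity slope: negative for ordinary persistence decay, positive
("negative friction") when slow cells tend to accelerate, the signature of
constricted two-state migration.  `hopping_times()` runs a hysteretic
two-threshold state machine (entry at
$\pm(x_\text{threshold} + \text{hysteresis}/2)$; defaults 8.5 µm and 4 µm —
the bridge half-length minus $R_0/2$, with a guard band), discarding the
incomplete first and last dwells.  `occupancy_fractions()` computes the
area-weighted occupancy
$P_\text{left} = (T_L/A_L) / (T_L/A_L + T_R/A_R)$, excluding bridge time
($|x| \le$ bridge half-length) — whether bridge transits should count toward
a basin is genuinely ambiguous, so exclusion is the default and the split is
configurable.

## Problem sizes used in the checks

The automated checks run a 1-hour default two-state simulation for the area
constraint, a 40-minute relaxation for the equilibrium radius, 200–400
48-hour OU fixtures for drift recovery, analytic drift fields for the
classifier gate, and a 20 × 12-hour default ensemble for the hop statistics
— deliberately far below the thousands of 48-hour runs a full study would
use; the configs for full-scale ensembles ship in `inst/extdata/`.  At the
reduced scale, stochastic summaries (hop counts, bridge statistics) carry
sampling noise that the full-scale study would average away.

## What the synthetic generator does not emulate

The SDE fixtures share the trajectory format and cadence of the simulator
but have stationary, spatially homogeneous noise and no geometry; passing
drift recovery on them validates the estimator's arithmetic, not the
identifiability of cell dynamics from 12-hour confined trajectories.
Likewise the phase-field model itself omits a nucleus (the centre of mass
stands in for the tracked nuclear position), any adhesive energy between
cell and pattern (confinement is purely a signalling effect), polarity
advection with the boundary, and multi-cell interactions.
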