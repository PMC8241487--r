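---
title: "Models and estimators for fire ant raft treadmilling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for fire ant raft treadmilling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftmill)
```

## The system and the quantities this package computes

A floating fire ant raft is a two-state aggregate: a planar *structural*
network of interlinked ants riding on the water, and a dispersed layer of
*free* ants walking on top of it. Anchored rafts reach a treadmilling
pseudo-steady state driven by three simultaneous processes:

* the structural network contracts isotropically at a linear strain rate
  $\dot\varepsilon$ (so a tracked material area decays as
  $A_r = A_{r0}\,e^{-2\dot\varepsilon t}$);
* structural ants exit into the free layer throughout the bulk at rate
  $\delta = 2\rho_r\dot\varepsilon$ per unit area ($2\dot\varepsilon$ per
  structural ant), the unique rate that keeps the network density $\rho_r$
  constant while the area shrinks;
* free ants deposit into the network at the raft edge at rate $\gamma$
  per unit perimeter, equivalently $\alpha = \gamma P / A$ per unit area.

`raftmill` implements (i) the trajectory statistics used to characterize
the free layer as self-propelled particles, (ii) the estimators of
$\dot\varepsilon$, $\delta$, $\gamma$, $\alpha$ and the protrusion
metrics $V$ and $W$, (iii) a simulator of self-propelled particles in
strongly confining convex domains, and (iv) the curvature- and
bias-driven boundary-growth model of protrusion instabilities. A
synthetic-data module generates inputs with the statistical structure the
estimators assume, because the original image-tracked ant data have no
public accession.

All lengths are in average ant body lengths ($\ell$), data-level times in
seconds, and rates are reported per minute. A single scalar
(`density_mm2_to_ell2()`, default body length 2.9 mm) bridges the two
density conventions (ants mm^-2^ vs ants $\ell^{-2}$).

## Free-ant trajectory statistics

`compute_velocities()` forms finite-difference velocities
$v = [x(t+\Delta t) - x(t)]/\Delta t$ across consecutive frames of the
same individual; the ensemble mean speed is the $v_0$ estimate.
Zero-speed records have no defined direction and are excluded from every
direction-based statistic (they still count in the mean speed).

`msd_analysis()` forms the ensemble mean-square displacement over all
ants and overlapping start times and fits
$\langle x^2\rangle = 4 D \tau^\xi$ in log-log space. Overlapping starts
maximize the sample count at the cost of correlated samples; this biases
no moment, only the nominal degrees of freedom.

`persistence_length()` bins the directional autocorrelation
$\langle\hat v_0\cdot\hat v_\tau\rangle$ by distance travelled and fits
$\exp(-l_c/l_p)$ by linear least squares on the log. Two ensembles are
offered. The per-ant mode (default) fits each individual and reports the
mean of the per-ant values, the way a distribution over individuals is
usually presented; but the reciprocal of a noisy slope is upward-skewed,
so for *parameter recovery* the pooled mode — one fit to the
all-observation ensemble — is the right tool, and it is what the
package's own recovery tests use. Perfectly straight paths leave the
correlation at 1 everywhere; the fit is then flagged `saturated` and
$l_p = \infty$ rather than a spurious finite value. Edge-encountering
ants can be excluded with a polygonal mask and a margin (default
2 $\ell$); the detection length scale of a wall is not measurable from
trajectories alone, so the margin is a user parameter, not an estimate.

`pair_correlation()` computes
$c(\sigma, \tau) = \langle\hat v_i(t)\cdot\hat v_j(t+\tau)\rangle$ with
the separation $\sigma = |x_i(t) - x_j(t+\tau)|$ taken at the two
different times — the statistic's defining (if unusual) convention; a
same-time-separation variant sits behind `same_time = TRUE`. Bins with no
pairs are `NA`, never zero. A subtlety worth knowing: conditioning on
separation induces genuine correlation in ensembles whose displacements
are comparable to their spread, so "no correlation" null checks must use
tracks short relative to the ensemble extent.

`velocity_metric_tensor()` computes
$g^v = \langle \hat v \otimes \hat v\rangle$. Unit vectors force
$\mathrm{tr}\,g^v = 1$ exactly, so isotropic traffic gives
diag(0.5, 0.5) and the eigenvalue gap measures directional bias; the
principal axis is oriented by the net displacement and the second axis
right-handed.

`order_parameter_scan()` tiles the data bounding box with $L \times L$
squares from its lower-left corner and averages
$|\varphi| = |\langle v\rangle|/\langle|v|\rangle$ over squares holding
at least two ants — single-occupant squares are trivially ordered and
excluded. Squares truncated by the boundary are kept if they hold two
ants; the tiling origin is a convention and stated as such.

## Treadmilling rate estimators

`fit_area_decay()` fits $\log A_r$ linearly in time (exact on noiseless
exponentials, the reason it is the default) with a nonlinear refit as an
option; `fit_radial_strain()` fits $\dot R$ on $R$, whose slope is
$\dot\varepsilon$ under isotropic anchored contraction and whose
intercept diagnoses non-anchored flow. `exit_rate()` applies
$\delta = 2\rho_r\dot\varepsilon$. `edge_deposition_rate()` differences
the growth area, $\gamma = \dot A_g \rho_r / P$, using the trapezoid of
the perimeter across each interval, and reports $\alpha$ in both
per-unit-area and per-structural-ant variants because both conventions
appear in field use (they differ by the factor $\rho_r$). If the growth
area exceeds 20% of the raft the estimator warns: at that point the
assumption that exits inside the growth zone are negligible weakens, and
the tracked edge set should be re-traced.

`protrusion_metrics()` measures a protrusion from a tip track, two flank
reference points and an outline polygon: $L$ is tip-to-mean-flank
distance, $V$ its finite-difference rate, and $W \approx A_p / L_c$ with
the centerline length $L_c$ taken as the outline's extent along its
principal axis (the measurement the width definition needs but that field
protocols leave unstated). Local contraction of the flank references is
not corrected; it is an order of magnitude below tip growth.

## The synthetic-data generators

`gen_abp_trajectories()` produces active Brownian walkers: constant speed
$v_0$, heading increments Gaussian with variance $2\,dt/\tau_r$ (standard
rotational diffusion). Defaults are the measured free-ant values
($v_0 = 0.59\ \ell\,s^{-1}$, $\tau_r = 34$ s). The generator makes no
attempt to emulate the interstitial sub-/super-diffusive switching real
ants show; its $\xi$ is the clean ABP crossover, so tests against it
validate estimators, not ant behaviour.

`gen_contracting_raft()` builds a disc of structural ants at density
$\rho_r$ (default 2.54 $\ell^{-2}$), advects them by the exact
exponential contraction map each frame (so decay-fit tests are not
confounded by integrator error), converts ants to the free layer as a
Poisson process at $2\dot\varepsilon$ per ant, and deposits new
structural area at the perimeter as a Poisson process at $\gamma$ per
unit perimeter (defaults $\dot\varepsilon = 1.75\%$ min^-1^,
$\gamma = 0.29$ min^-1^ $\ell^{-1}$, one-hour duration — the scale of
observed protrusion cycles). Three deliberate idealizations keep every
estimator identifiable from one run: the tracked-edge area $A_r$ is the
advected material perimeter curve (so it decays exactly exponentially);
the growth rim does not itself contract within a run (its contraction is
second-order in $\dot\varepsilon\,t$ relative to the deposition signal,
and letting it contract makes $\gamma$ unidentifiable from a
full-duration $A_g$ series — the field protocol instead re-traces the
edge periodically); and deposited ants are not further tracked. The
generator therefore conserves network density exactly in expectation,
and its event tallies (`exit_tally`) provide the brute-force oracle for
$\delta$.

`gen_strip_walkers()` adds a uniform drift along a reflecting strip to
emulate the directionally biased traffic seen on narrow protrusions;
tests tune the drift by root finding until $g^v_{11}$ matches a target
anisotropy.

## Self-propelled particles in strong confinement

`simulate_confined_spp()` integrates overdamped, translationally
noiseless particles: ballistic interior motion at $v_0$, rotational
diffusion of the heading, wall attachment on contact, wall gliding, and
detachment when the heading points inward. For the glide law we use the
tangential projection $\dot s = v_0(\hat e(\theta)\cdot\hat t)$. The
printed convention $\dot s = v_0\cos(\theta - \psi)$ with $\psi$ the
*normal* orientation is maximal when the particle pushes straight into
the wall, which contradicts the geometry of gliding; it equals the
projection form when the angle is measured from the tangent, and we read
it that way, keeping the literal form available via
`glide = "normal_angle"`. The time step defaults to
$\min(\tau_r/50,\ 0.1\,\text{feature}/v_0)$ to resolve both reorientation
and wall curvature.

In the strong-confinement limit ($l_p$ exceeding the confining
dimension) the stationary wall density is curvature-weighted,
$\rho_s(s) = \kappa(s)/2\pi$ (`fily_steady_density()`), integrating to
exactly 1 around any closed convex boundary because the total turning is
$2\pi$. `boundary_residence_density()` histograms simulated wall
residents for comparison; on a 2:1 ellipse with $l_p$ about six times
the width the simulated density correlates with $\kappa/2\pi$ at
$r > 0.99$, and weak confinement demonstrably flattens it.

## The protrusion growth model

The model evolves an open boundary mesh (initially the distal half of an
ellipse, full axes 2.5 $\ell$ by 5 $\ell$, so semi-axes 1.25 and 2.5 and
analytic tip curvature $a/b^2 = 1.6\ \ell^{-1}$) under the deposition
field
$$\gamma(s) = \Big[a\,\frac{\rho_s}{\rho_0} + \gamma_0\Big]\,
\frac{\hat n + \beta\hat\varphi}{|\hat n + \beta\hat\varphi|},\qquad
\rho_s = \frac{\max(\kappa, 0)}{2\pi},$$
stepped by forward Euler via $\rho_r\,dx/dt = \gamma$, with
arclength-uniform cubic remeshing (0.1 $\ell$ spacing) every step and
endpoints sliding along the baseline $y = 0$ (curvature there is
computed with a mirror continuation across the baseline; if the curve
degenerates onto the baseline the continuation falls back to point
reflection). The bias $\beta$ redirects deposition toward
$\hat\varphi = (0, 1)$ without changing its magnitude; the clamp in
$\rho_s$ keeps concave stretches (possible near the base late in a run)
from hosting negative crowd density, and never activates on the initial
shape.

**Unit convention.** The deposition law's normalization $a = v_0/\ell^2$
is stated in min^-1^ $\ell^{-1}$ while the free-ant speed is measured in
$\ell\,s^{-1}$, and the density $\rho_r$ enters in unstated units; the
full parameter table of the original model is not available. We resolve
this as $a = 0.59$ min^-1^ $\ell^{-1}$ (the numerical speed value carried
per minute) and $\rho_r = 2.54\ \ell^{-2}$, the combination under which
the unbiased run respects the reported bounds on tip speed; both are
plain `growth_params()` arguments and the CLI logs the resolved values.
The alternative reading $a = 35.4$ min^-1^ $\ell^{-1}$ ($v_0$ in
$\ell$/min) makes $\partial v/\partial\kappa$ sixty-fold larger and the
front then suffers a violent short-wavelength instability (growth rate
increasing with wavenumber, the Mullins–Sekerka pattern) that
self-intersects the mesh long before 480 s at any stable step; it is not
tenable under this discretization. A consequence of the adopted
convention is that the biased run's tip extension rate stays well below
1 $\ell$/min: the bias-monotone response and the $\beta = 10$ sharpening
(tip curvature beyond 1 $\ell^{-1}$) are reproduced, the absolute
$\beta = 1$ rate is not.

**Numerical choices.** Curvature is $\partial\psi/\partial s$ by centered
differences with an arclength moving average over 0.5 $\ell$ — about one
ant length, below which the continuum description has no meaning anyway;
reported "tip curvature" is this smoothed value at the
extension-maximizing vertex (ties broken toward the bias ray through the
initial tip). The stability guard rejects steps moving any vertex more
than a quarter of the remesh spacing. At the defaults the scheme matches
the scalar radius ODE for a closed circle to $10^{-6}$ relative and
halving $dt$ changes $L(480\,\mathrm{s})$ by 0.01%. Resolution finer
than ~0.1 $\ell$ combined with weaker smoothing re-admits the physical
short-wavelength instability and is rejected by the self-intersection
check rather than silently producing garbage.

## Problem sizes in the tests

The shipped tests run the generators at: 200–400 ABP walkers for a few
hundred seconds (speed and persistence recovery, diffusive closed form);
800–1000 structural ants for 30–60 simulated minutes (density
conservation, rate recovery); 100 confined particles for 2000 s on the
2:1 ellipse (wall accumulation); and the full 480-step bias sweep at 512
initial vertices. These sizes put Monte-Carlo scatter comfortably inside
the stated recovery tolerances (5% on $v_0$, $\dot\varepsilon$, $\gamma$;
25% on $l_p$; Poisson bounds on event tallies) while keeping the whole
suite in well under a minute of compute per module.

## What passing tests do and do not show

The generators realize exactly the stochastic models the estimators
assume: recovery therefore validates correctness of the implementations
and their mutual conventions (units, factor-of-two bookkeeping between
linear and areal rates), not the adequacy of those models for real ants.
Real rafts violate the generators in known ways — free ants cluster and
jam at packing fractions above ~0.3, diffusivity varies along a
trajectory, the contraction field fluctuates, and deposition is discrete
at the ant scale — and none of these features is emulated. Where a
reported field value depends on the original footage (e.g. mean
$\xi \approx 1.48$, $l_p = 17.3\ \ell$), the package reproduces the
*machinery* that produced it, and the tests check parameter recovery on
synthetic ground truth instead.
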