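---
title: "Hyperbolic maps of temporal proximity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic maps of temporal proximity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperprox)
```

This vignette is the package's account of its science: the generative model
it assumes, the estimators it implements, the parameters that matter, and
the numerical and design choices behind them.

## The static S¹ model

A snapshot of a proximity system is modelled as a random geometric graph on
a circle. Node $i$ carries two latent variables: a hidden degree
$\kappa_i > 0$, proportional to its expected number of contacts, and an
angular similarity coordinate $\theta_i \in [0, 2\pi)$ on a circle of radius
$R = N/2\pi$. A pair connects independently with the Fermi–Dirac probability

$$p(\chi_{ij}) = \frac{1}{1 + \chi_{ij}^{1/T}}, \qquad
  \chi_{ij} = \frac{R\,\Delta\theta_{ij}}{\mu\,\kappa_i\kappa_j},$$

where $\Delta\theta_{ij} = \pi - |\pi - |\theta_i - \theta_j||$ is the
circle distance and the temperature $T \in (0,1)$ controls how sharply
connection probability decays with effective distance $\chi$ (small $T$:
strong clustering, near-deterministic geometry; $T \to 1$: weak coupling to
the metric). The constant

$$\mu = \frac{\bar k \sin(T\pi)}{2\bar\kappa^2 T\pi}$$

calibrates the expected mean degree to a target $\bar k$, with $\bar\kappa$
the mean of the hidden-degree law. Three hidden-degree laws are supported
(`kappa_delta`, `kappa_powerlaw`, `kappa_empirical`); the delta law yields
near-Poisson snapshot degrees, the Pareto-type law scale-free ones, and the
empirical law reproduces observed per-node activities. The model is
equivalent to a random hyperbolic graph: with $\kappa_0 = \min_i \kappa_i$
and disk radius $\hat R = 2\ln[N/(\pi\mu\kappa_0^2)]$, the change of
variables $r_i = \hat R - 2\ln(\kappa_i/\kappa_0)$ satisfies
$\chi_{ij} = e^{(x_{ij} - \hat R)/2}$ with
$x_{ij} = r_i + r_j + 2\ln(\Delta\theta_{ij}/2)$ approximately the
hyperbolic distance (`to_hyperbolic` checks this identity to $10^{-9}$
relative in the tests).

## The dynamic-S¹ model and time aggregation

A temporal network is a sequence of $\tau$ snapshots over *fixed*
coordinates: every slot $t$ is an independent S¹ draw with its own mean
degree $\bar k_t$ (edges are deleted between slots). Two consequences drive
everything else:

- **Durations.** Per pair, slot occupancy is i.i.d. Bernoulli, so contacts
  (maximal runs of occupied slots) and intercontacts (maximal gaps between
  contacts) are geometric per pair; mixing over the heterogeneous per-pair
  rates produces power-law duration distributions with exponents $2+T$
  (contacts) and $2-T$ (intercontacts). `fit_powerlaw_discrete` (discrete
  MLE with lower cutoff 1, zeta normalizer) recovers both within $\pm 0.15$
  on generated data; gaps before the first or after the last contact are
  censored and excluded, the standard convention.
- **Aggregation.** With constant $\bar k_t$, the probability that a pair is
  connected in *at least one* of $\tau$ slots is exactly
  $P(\chi) = 1 - (1 - p(\chi))^\tau$; for $\tau \gg 1$ this approaches
  $1 - \exp[-(\Gamma(1+T)/\tilde\chi)^{1/T}]$ in the rescaled distance
  $\tilde\chi = \chi/\alpha$, $\alpha = \tau^T/\Gamma(1+T)$, which behaves
  like a Fermi–Dirac curve at both small and large distances (tail
  $C/\tilde\chi^{1/T}$ with $C = \Gamma(1+T)^{1/T}$). A node's expected
  aggregated degree is $\tilde\kappa = \alpha\kappa$ in the thermodynamic
  limit, the hinge that converts aggregated inferences back to per-slot
  scale (`per_slot_kappa`). Because $0.88 < \Gamma(1+T) < 1$ on $T \in
  (0,1)$, $\alpha$ is essentially $\tau^T$.

Both generation paths are exact: with constant $\bar k_t$ the generator
draws each pair's occupancy count from Binomial($\tau$, $p$) and places the
occupied slots uniformly (identical in law to slot-by-slot sampling, and an
order of magnitude faster); heterogeneous $\bar k_t$ profiles are generated
slot by slot with $\mu$ recalibrated per slot at fixed $\bar\kappa$.
`sample_aggregated_s1` samples the aggregated graph directly from the exact
$P(\chi)$ when the temporal network itself is not needed.

The $\tilde\kappa = \alpha\kappa$ scaling carries a caveat the package
surfaces deliberately: it assumes no degree cutoff, so at finite $N$ and
large $T$ (fat connection tails) the realized aggregated degrees fall short
of $\alpha\kappa$ — about 5% at $N = 1000$, $T = 0.7$ even at aggregated
degree 5, and worse as $\alpha\bar\kappa$ approaches $N$.
`calibrate_temperature` warns when its target enters that saturation
regime, and the degree-scaling validation pins every condition at
aggregated mean degree 5, far below the cutoff.

## Embedding the aggregated graph

`embed_graph` inverts the synthesis on the largest connected component
(zero-degree nodes and minor components carry no likelihood signal and are
excluded, listed in `excluded`). Four stages:

1. **Temperature** (`infer_temperature`). Mean local clustering is the
   temperature's fingerprint. For candidate $T$ on a 0.05 grid (with one
   ±0.025 refinement, clamped to $[0.05, 0.95]$), hidden degrees are
   re-inferred and a small synthetic ensemble (3 graphs) generated; the $T$
   whose ensemble clustering best matches the observed value wins.
   Recovery on generated graphs is within ±0.1; the downstream pipeline
   tolerates errors of ±0.2 because the likelihood surface in $T$ is flat
   relative to the angular structure.
2. **Hidden degrees** (`infer_latent_degrees`). $\tilde\kappa$ solves the
   fixed point "model-expected degree (angles integrated out) = observed
   degree". Expected degrees depend on a node only through
   $\tilde\kappa_i$ and the multiset of all $\tilde\kappa_j$, so the system
   is solved on unique degree values only. Updates are multiplicative with
   adaptive damping (halved on overshoot); convergence tolerance $10^{-3}$
   relative. A hub with degree $N-1$ has no finite solution (its expected
   degree approaches $N-1$ only as $\tilde\kappa \to \infty$); such graphs
   need a looser tolerance, which the function exposes.
3. **Initial angles** (`initial_angles_le`). Laplacian Eigenmaps on the
   edge-weighted graph with weights $1/\sqrt{\tilde\kappa_i\tilde\kappa_j}$
   (hubs connect far and carry less angular information): the two leading
   non-trivial eigenvectors of the symmetric normalized Laplacian give
   $\theta_i = \mathrm{atan2}(v_{2i}, v_{1i})$. On a cycle graph this is
   exact; on S¹ graphs it already places most nodes within ~0.15 rad.
4. **Refinement** (`refine_angles_mle`). Coordinate ascent on the Bernoulli
   log-likelihood, nodes visited in decreasing degree order; per node the
   candidates are its current angle, its neighbors' circular mean, eight
   wrapped-Gaussian proposals, and a 16-point uniform grid; the best
   candidate is kept, so the total log-likelihood never decreases. Sweeps
   stop when a full sweep gains less than $10^{-3}$, capped at 10.

The likelihood can be the plain Fermi–Dirac form (`mode = "fermi_dirac"`,
the default — simpler and requiring no knowledge of $\tau$) or the exact
finite-$\tau$ aggregated form (`mode = "aggregated"`); at $\tau = 1$ the two
coincide up to the fixed $\alpha$ rescaling of distances. Both modes share
$\tilde\mu$ computed from the observed mean degree via the $\mu$ formula
above, so inferred distances $\tilde\chi$ are directly comparable to the
theoretical curves.

One optimization choice deserves its own paragraph. The angular likelihood
has families of near-degenerate optima that differ by smooth *warps* of the
circle — compressing dense sectors and stretching sparse ones raises the
in-sample likelihood slightly while moving every coordinate away from the
truth. A proposal scale that narrows across sweeps reliably grinds into
such warped optima (mean angular error roughly doubles); keeping the
wrapped-Gaussian proposal scale *constant* at $\pi/2$ makes fine,
correlated micro-moves unlikely to be proposed and holds the ascent in the
well-structured basin found by the spectral initialization. The package
therefore uses a constant proposal scale. The gauge freedoms proper —
global rotation and reflection — are exact likelihood invariances and are
handled at evaluation time, never during fitting.

## Evaluation

`procrustes_align` removes the rotation/reflection gauge before errors are
measured: a dense rotation grid (step $10^{-3}$ rad, both orientations)
plus local refinement minimizes the summed squared circular distance.
`d_kappa` and `d_theta` are mean absolute errors (circular distance for
angles, post-alignment, hence gauge-invariant and bounded by $\pi$).
`aggregation_sweep` traces both errors and the aggregate density against
the window length $\tau$: too few slots leave too sparse a graph, too many
drive the aggregate toward completeness where "all nodes look the same";
between the two extremes lies a wide usable plateau. At the
primary-school-like scale ($N = 242$, $\tau = 2584$, $T = 0.72$,
homogeneous $\kappa = 0.18$, density ≈ 0.17) the default pipeline lands at
$D_\kappa \approx 0.04$ and $D_\theta \approx 0.08$ rad, comfortably inside
the 0.2 bounds the validation asserts.

## Applications on the temporal network

**Routing.** In H2H-GR a carrier forwards the packet to its current
neighbor closest (in $\tilde\chi$) to the destination, only if that
neighbor is strictly closer than itself, delivering immediately when the
destination is in range; strict distance decrease makes routes loop-free.
Within a slot, forwarding repeats until the packet cannot move (the
snapshot is treated as a static graph; the protocol definition fixes no
per-slot hop budget, and this convention makes $\tau = 1$ reduce to
ordinary static greedy routing); packets launch at the window's first slot
and an undelivered packet at window end is a failure. Ties are broken by
smallest node id, making H2H-GR fully deterministic. H2H-RR forwards
uniformly among neighbors that never held the packet. Stretch is measured
against minimum-hop time-respecting paths (successive edges in
non-decreasing slot order, multi-hop within a slot allowed), computed by a
hop-layered earliest-arrival relaxation. A `distance = "similarity"` flag
routes on angular distance alone. Packets are treated independently
(whether concurrent packets would interact within a slot is left open by
the protocol definition; independence is the simplest reading and is
documented here).

**Link prediction.** Pairs co-present (non-zero degree) in both windows are
scored by $s = 1/\tilde\chi$ from previous-window coordinates, or by
common-neighbor counts; labels come from the target window's aggregate.
All co-present pairs are scored by default — whether pairs already linked
in the previous window should be excluded is genuinely ambiguous, so an
`exclude_known` flag exposes the alternative. AUROC uses the Mann–Whitney
convention (ties count one half) and must agree with the threshold-sweep
curve to $10^{-9}$ (two internal routes, cross-checked against pROC in the
tests); AUPR is average precision with step interpolation, whose chance
level equals label prevalence.

**Epidemics.** Discrete-time SI: a susceptible node in contact with $m$
infected neighbors in a slot becomes infected with probability
$1-(1-\beta)^m$ — independent Bernoulli attempts per contact, the natural
combination rule when the protocol specifies only a per-contact
probability. Updates are synchronous at slot end (no same-slot chains),
the standard discrete-time convention; both choices are seed-stable.
`arrival_vs_distance` bins hyperbolic distance from the source (width 1,
bins under 5 samples dropped — matching the analysis conventions of the
arrival-time literature), and `epidemic_experiment` reports the mean
Spearman rank correlation between arrival slot and distance across runs
from random sources at $\beta = 0.05$ per slot. The distance
$x = r_s + r_i + 2\ln(\Delta\theta/2)$ is clamped below at $|r_s - r_i|$,
the exact hyperbolic distance of angularly coincident nodes, which keeps
coincident-angle pairs finite.

## What the generator emulates, and what it does not

The synthetic module reproduces the features that make proximity data hard:
extremely sparse snapshots (per-slot mean degrees of order 0.1), heavy-
tailed contact/intercontact durations, dense aggregates with latent
geometry, and day-scale non-stationarity via per-slot degree profiles
(`kappa_empirical` + per-slot $\bar k_t$ reproduce a real network's
activity profile, with the counterpart temperature calibrated by bisection
on the predicted aggregated mean degree). It does **not** emulate: motion
of coordinates over time (real systems' coordinates drift between days;
the model holds them fixed, which is exactly why previous-day coordinates
work better on synthetic counterparts than on real data), slot-to-slot
edge persistence beyond what fixed geometry induces, group scheduling
(classes meeting at fixed hours), or measurement artifacts (sensor
dropout). Passing validation on these fixtures therefore demonstrates
correctness of the machinery and self-consistency of the estimators — not
that any particular real system satisfies the model's assumptions.

## Numerical choices

- Expected-degree integrals use 96-point Gauss–Legendre quadrature in
  $\log\Delta\theta$ over $[10^{-12}, \pi]$ (the connection kernel's
  transition scale $\mu\kappa_i\kappa_j/R$ spans many orders of magnitude
  across pairs; a linear grid cannot resolve it), with the missed
  $[0, 10^{-12}]$ head, where $P = 1$, added in closed form.
- Likelihood probabilities are clamped to $[10^{-15}, 1-10^{-15}]$ so
  missing far edges keep finite penalties.
- Angles are stored half-open in $[0, 2\pi)$; all inputs are reduced
  modulo $2\pi$; pairs with $\kappa_i\kappa_j = 0$ get $\chi = \infty$
  (never connect).
- The temperature-calibration bisection runs on the deterministic
  quadrature prediction, not on simulations, so it is noise-free and
  monotone; pair universes larger than 20k are thinned to an evenly spaced
  subset.
- Eigenvector ties (exactly zero entries) in the spectral initialization
  are broken by $10^{-6}$ jitter under the run seed.
- All stochastic entry points take an explicit `seed` and restore the
  caller's RNG state, so library calls never perturb user-level
  reproducibility.

## Problem sizes

The validation suite runs at reduced but faithful scales chosen so the full
suite completes in a few minutes on one core: recovery at the
primary-school scale ($N = 242$, $\tau = 2584$), degree scaling at
$N = 1000$ with $\tau \in \{500, 2000\}$ sampled directly from the exact
aggregated law, duration exponents at $N = 500$, $\tau = 5000$, and
routing/prediction/epidemic experiments at $N \in [100, 150]$ with windows
of 600–6000 slots. Epidemic windows are long enough for outbreaks to reach
most of the network, because the per-run rank correlation is uninformative
for small outbreaks.

## Known limitations

- The embedding targets networks up to a few thousand nodes (dense
  adjacency matrices and full eigendecompositions); proximity systems are
  comfortably inside that envelope.
- Temperature estimates inherit the bias of the clustering-matching
  criterion under model misspecification (the plain Fermi–Dirac mode
  applied to an aggregated graph typically estimates $T$ below the
  generating value — the aggregated curve is steeper near its midpoint —
  without materially hurting coordinate recovery).
- The $\tilde\kappa = \alpha\kappa$ conversion degrades near degree
  saturation, as discussed above.
- Components other than the largest are not embedded; their nodes are
  excluded from routing/prediction universes rather than given fallback
  coordinates.
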