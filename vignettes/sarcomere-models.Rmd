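---
title: "Reduced Markov models of sarcomere force generation: methods and design"
author: "sarcodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced Markov models of sarcomere force generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcodyn)
```

## The biophysical picture

Active force in cardiac muscle is produced by two coupled protein systems
inside the sarcomere.  Regulatory units (RUs) -- troponin/tropomyosin
complexes spaced regularly along the thin (actin) filament -- act as
calcium-operated switches: troponin binds Ca2+ (states U/B) and tropomyosin
shifts between a non-permissive (N) and a permissive (P) configuration.
Neighbouring tropomyosin units interact end-to-end, which makes activation
cooperative: the steady force-calcium curve is much steeper than a
one-site binding law (Hill coefficient well above one).  When a RU is
permissive, myosin heads from the thick filament can attach to the adjacent
actin binding site and form a crossbridge (XB), a linear spring of strain
`x` whose cycling generates tension.

The natural description is a continuous-time Markov chain over every RU and
every head.  Its state space is astronomically large (order 10^60 for a
filament pair), so models of this class are usually simulated by Monte
Carlo at great cost.  This package implements deterministic reductions of
that chain that need no stochastic sampling:

* **SE (spatially explicit) family** -- every RU along the filament is
  represented, with position-dependent rates through smooth overlap
  weights.  The RU chain is closed at the level of joint distributions of
  *triplets* of consecutive units, assuming distant units are conditionally
  independent given the intermediate ones (the interaction is
  nearest-neighbour, so this discards only secondary long-range
  correlations).  State count: `(n_ru - 2) * 64` triplet probabilities.
* **MF (mean-field) family** -- the single-overlap zone is treated as
  translation invariant and one representative triplet is tracked (16
  probabilities, since only the central troponin state is kept).  Overlap
  enters the force multiplicatively through the single-overlap ratio.
* **ODE vs PDE crossbridge description** -- the attached-XB strain
  distribution either evolves as a transported density `n_P(x), n_N(x)`
  (PDE variants, first-order upwind in `x`), or, when the total
  attachment + detachment rate is strain-independent
  (`f + g = r(v) = r0 + alpha |v|`, a modelling choice, not an
  approximation), collapses exactly to its first two moments
  (ODE variants).  The MF-ODE model has 20 states; the SE-ODE model 2048
  at the default 32 RUs.

Active tension is `T_a = a_XB * mu^1`, with `mu^1` the mean normalised XB
strain moment (overlap-weighted in the MF family, averaged over units in
the SE family).

## Transition rates

All RU rates are generated from six named constants, never entered by
hand, so the four-state cycle is thermodynamically consistent (every loop
product of forward/backward ratios is one):

| rate | value |
|---|---|
| Ca binding (N or P) | `(koff / kd) * Ca` |
| Ca unbinding | `koff` (N), `koff / mu` (P) |
| N to P | `(Q/mu) kbasic gamma^n` (U), `Q kbasic gamma^n` (B) |
| P to N | `kbasic gamma^(2 - n)` |

where `n` counts permissive nearest neighbours and `gamma` encodes the
end-to-end coupling energy (`gamma = exp(2 dE / kB T)`).  Missing
neighbours at filament ends count as non-permissive -- in the SE family
this single boundary convention is what produces emergent length-dependent
activation (see below).  In the spatially explicit family the N-to-P rate
of unit `i` is multiplied by the single-filament weight `chi_SF(SL, i)`
(tropomyosin cannot open where the two thin filaments overlap), and XB
attachment is additionally weighted by `chi_M(SL, i)` (the unit must face
the thick filament).  Both weights are tanh ramps of width `eps = 0.05` um.
The mean-field family instead carries a phenomenological linear length
dependence of the calcium sensitivity,
`kd(SL) = kd_bar + alpha_kd (SL - SL_kd)` with `SL_kd = 2.15` um, clamped
below at `0.05 kd_bar` because the linear law is otherwise unguarded at
extreme lengths.

The aggregated (closure) rates for the edge units of a stored triplet are
conditional expectations over the neighbouring triplet's distribution.
When a conditioning probability falls below `eps_den = 1e-12` the
aggregated rate is returned as zero: the flux it multiplies is itself of
that vanishing order, so the choice cannot affect the visible dynamics.
The same rule covers the permissivity-conditioned coupling rates at
`P = 0` or `P = 1`.

## Parameters

Two calibrated presets ship with the package (`sarcomere_preset()`):
room-temperature rat and body-temperature human, for each family.  The
XB constants (`r0 = 134.31` 1/s, `alpha = 25.184`, `a_XB = 22.894` MPa,
and the attachment moments `mu_fP0`, `mu_fP1`) are shared across species;
the families differ in cooperativity (`gamma` 20 SE / 12 MF), bias
(`Q` 3 / 2) and calcium sensitivity (`kd_bar`), and the human sets have
slower kinetics (`kbasic`, `koff`) and higher sensitivity, reflecting
isoform and temperature differences.  Geometry defaults: `SL0 = 2.2`,
`LA = 1.25`, `LM = 1.65`, `LH = 0.18`, `eps = 0.05` um, 32 RUs, 18 heads
per half filament.  The inter-head spacing, needed only by the PDE
variants, defaults to `DM = (LM - LH) / (2 n_mh)` (heads evenly spaced
along one half of the head-bearing region); the ODE variants absorb `DM`
into the attachment moments.

## Numerical choices

* **Integration.**  Adaptive stiff solvers throughout (the RU rates reach
  `kbasic gamma^2 ~ 1e4` 1/s): `lsoda` for the 20-state mean-field model,
  `lsodes` with internally detected Jacobian sparsity for the large
  spatially explicit systems.  Defaults `rtol = 1e-6`, `atol = 1e-9` for
  the moments variants and `rtol = 1e-9`, `atol = 1e-12` for the
  strain-density variants (cheap there, and needed for the sparse solver
  to conserve probability tightly).  Conservation is algebraically exact
  in the right-hand sides; the integrator drift over a 10 s trajectory is
  below `1e-8` for the mean-field models and below `1e-5` for the
  per-triplet norms of the SE-ODE model at its default tolerance (the
  documented trajectory tolerance).
* **Steady states.**  Crossbridges do not feed back on the RUs, so steady
  protocols equilibrate the RU block alone and then solve the linear
  moment (or per-node density) equations in closed form.  The mean-field
  RU steady state uses a self-consistent-field iteration: freeze the
  aggregated edge rates, solve the resulting linear 16-state master
  equation exactly, update, repeat to `1e-12`; iterates stay on the
  probability simplex by construction.
* **PDE discretisation.**  First-order upwind transport with zero inflow
  on `x in [-0.05, 0.06]` um, 401 nodes by default (the attachment support
  sits near `x ~ 21-31` nm); the attachment profile is evaluated as cell
  averages so its discrete zeroth moment is exact on any grid.  The
  default profile is rectangular with height `r0`: it is the minimal shape
  whose two free constants (width, centre) match the two prescribed
  moments exactly, and it keeps the paired detachment rate nonnegative.
  A triangular alternative is available.  The implicit method-of-lines
  path has no CFL restriction; the optional explicit path enforces
  `dt |v_hs| / dx <= 1` and errors otherwise.
* **Initial conditions.**  All RUs non-permissive and calcium-free, no
  attached crossbridges; configurable by passing `y0`.

## Virtual experiments

`force_calcium_curve()` and `force_length_curve()` use the fast steady
path; Hill fits (`Ta_max / (1 + (EC50/Ca)^nH)`) use Levenberg-Marquardt
least squares.  `isometric_twitch()` starts from the diastolic steady
state and reports peak tension, time to peak from stimulus onset, and the
times from peak to 50% and 90% relaxation towards the pre-twitch baseline
(linear interpolation between samples, parabolic peak refinement; metrics
are `NA` on a flat trace).  The calcium transient is a double exponential
normalised to peak `c_peak` -- rat defaults `c_dia = 0.1`, `c_peak = 1.0`
uM, `tau_rise = 0.02` s, `tau_decay = 0.11` s are a plausible synthetic
input, not a measured trace.

`force_velocity_curve()` freezes the regulatory state and overlap at their
isometric values by default and solves the linear moment equations at each
velocity -- mirroring the experimental practice of reading the tension
plateau before appreciable length drift; a free-running mode integrates
the full model over a short window instead.  Summing the permissive and
non-permissive moment equations cancels the regulatory coupling exactly,
so the normalised curve is `(1 - v rho / r(v)) r0 / r(v)` with
`rho = mu_fP0 / mu_fP1`, independent of activation -- the model thus
reproduces the experimental invariance of the normalised curve, and the
zero crossing `v_max = mu_fP1 r0 / (mu_fP0 - alpha mu_fP1)` (about 8.0 1/s
for the shipped constants) does not depend on calcium or length.
`fast_step_response()` applies a length step as a constant velocity over
200 us and reports end-of-step tension; positive steps stretch the half
sarcomere.  The moments models carry no instantaneous elasticity, so this
is a T2-type curve; purely elastic T1 behaviour is out of scope.

## Emergent length-dependent activation

In the spatially explicit family, units near the filament ends and the
single-filament boundary have at most one permissive neighbour, so their
permissivity is depressed; end-to-end coupling propagates the depression
inwards over a correlation length that grows with `gamma`.  At shorter
sarcomere length the suppressed zone is a larger fraction of the recruited
filament, so calcium sensitivity falls -- EC50 rises as SL drops with no
length-dependent parameter (`alpha_kd = 0` in the SE presets).  The
mean-field family, having no ends, cannot produce this and uses the
explicit `kd(SL)` law instead; its Hill coefficient is length-independent
by construction, while the SE family shows a mild increase with length.

## The exact oracle and what the closure loses

For chains of up to 10 units the package builds the full `4^n` sparse
generator, solves the stationary master equation by sparse LU, and runs a
seeded Gillespie sampler as a statistical cross-check.  Because the
constructed rates satisfy detailed balance, the stationary law is a
nearest-neighbour Gibbs field with the spatial Markov property -- so the
triplet closure is *exact at stationarity* for any `gamma`, a stronger
statement than the closure's derivation suggests, and the numerical
comparison at `n_ru = 6` confirms it to solver tolerance.  The closure's
approximation error lives in transients: 30 ms after a calcium step at the
rat SE constants the per-unit permissivity errors peak near 2e-3 (absolute,
`closure_error_report(..., t_eval = 0.03)`), and vanish as `gamma` tends
to one.  The oracle covers the RU subsystem; the crossbridge side is
validated instead through the PDE/ODE moment equivalence and the
frozen-activation closed forms, which is exactly the part of the model the
moments reduction is provably equivalent to.

## Staged calibration

The experimental setups decouple, which the pipeline exploits in three
sequential stages (re-running an earlier stage after a later one is a
fixed point):

1. **Crossbridges** (`calibrate_xb`): the stiffness ratio (instantaneous
   tension-elongation slope over isometric tension) fixes
   `rho = mu_fP0 / mu_fP1`; `(r0, alpha)` follow by least squares on the
   normalised force-velocity curve -- which is invariant under a common
   rescaling of `(r0, alpha, rho)`, so the curve alone cannot fix all
   three, and the function requires the stiffness target; the attached
   fraction pins `mu_fP0` and the isometric tension sets `a_XB` (without a
   duty-ratio target that split is underdetermined and the function says
   so).
2. **RU steady state** (`calibrate_ru_steady`): bound-constrained least
   squares of `(Q, mu, gamma, kd_bar, alpha_kd)` on force-calcium targets
   at two or more lengths.  Raw `(Ca, Ta)` samples are the recommended
   target form: the asymmetry of the curve about half activation is what
   identifies `(Q, mu)`; Hill triples discard it, leaving `kd_bar`
   identified only up to the exact ridge `EC50 = kd_bar h(Q, mu, gamma)`.
   On synthetic sample targets the stage recovers `gamma`, `kd_bar` and
   `alpha_kd` within 5%; 1-D misfit slices over the weakly identified
   `(Q, mu)` pair are emitted alongside.
3. **RU kinetics** (`calibrate_ru_kinetics`): seeded log-uniform
   Monte-Carlo sampling of `(kbasic, koff)`, scoring each pair by the L2
   misfit of normalised twitch traces.  The pair is poorly identified
   jointly -- a ridge of compensating (slower tropomyosin, faster calcium)
   combinations fits almost equally well -- so the full sample table is
   part of the result.  At 500 samples the best pair lands within about
   30% (`kbasic`) and 40% (`koff`) of the generating values, which is the
   tolerance the round-trip test asserts.

## Problem sizes used in the shipped tests

The validation suite exercises the full 32-RU geometry for the moments
models (10 s trajectories, steady curves, twitches) and scales the
heaviest configurations down to keep the suite brisk: the SE-PDE
conservation run uses 12 RUs with 81 strain nodes, the PDE/ODE equivalence
pair 8 RUs, the exact-oracle comparisons 4-6 units (the exact side grows
as `4^n`), and the stage-3 round trip 500 Monte-Carlo samples.  These
sizes are choices about where the checks are informative, not model
limits.

## What the synthetic tests do and do not show

All validation targets are generated by the models themselves or by exact
small-scale oracles: round trips demonstrate internal consistency,
correctness of the reductions, and identifiability structure -- they do
not validate the biology against new measurements.  The calcium transient
is an idealised pulse (no restitution, no length feedback on calcium, the
same transient at all lengths); filaments are rigid and inextensible;
there is no XB feedback on the RUs, no myosin off/super-relaxed state, no
titin or passive elasticity, and no power stroke (the models target
phenomena slower than it).  Within those limits the shipped presets
reproduce the canonical phenomenology: cooperative sigmoidal
force-calcium curves, plateau force tracking the single-overlap ratio,
length-dependent sensitivity (emergent or phenomenological), twitch
prolongation and peak growth with length, convex force-velocity curves
with an activation-independent `v_max`, and softening tension responses
to shortening steps.
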