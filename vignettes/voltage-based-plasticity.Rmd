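---
title: "A voltage-based model of synaptic plasticity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A voltage-based model of synaptic plasticity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbplast)
```

## The model

`vbplast` implements a phenomenological rule for long-term synaptic
plasticity in which the only postsynaptic signal is the time course of the
dendritic membrane potential `u(t)` near the synapse, expressed in mV
relative to rest.  The rule does not simulate a neuron: `u(t)` is an input,
either recorded experimentally or synthesized (see below).  Presynaptic
activity is a spike train `X(t)`; each spike increments a glutamate trace

$$\tau_x \frac{d\bar{x}}{dt} = -\bar{x} + X(t),$$

interpreted as transmitter bound to postsynaptic receptors; an isolated
spike switches `x_bar` from 0 to 1, after which it decays with `tau_x`.
The voltage is read through two first-order low-pass filters,

$$\tau_+ \frac{d\bar{u}_+}{dt} = -\bar{u}_+ + u, \qquad
  \tau_- \frac{d\bar{u}_-}{dt} = -\bar{u}_- + u.$$

Potentiation and depression accrue as rectified Hebbian products,

$$\frac{dw_{\rm LTP}}{dt} = A_{\rm LTP}\,\bar{x}\,[\bar{u}_+ - \theta_+]_+,
  \qquad
  \frac{dw_{\rm LTD}}{dt} = A_{\rm LTD}\,\bar{x}\,[\bar{u}_- - \theta_-(t)]_+,$$

and the weight changes as `dw/dt = dw_LTP/dt - dw_LTD/dt` from an initial
value `w_i = 0.5`.  The LTD threshold has a fixed part and a dynamic part,
`theta_-(t) = theta_0 + theta(t)`, with

$$\tau_\theta \frac{d\theta}{dt} = -\theta + b_\theta \frac{dw_{\rm LTP}}{dt}:$$

ongoing potentiation transiently raises the depression threshold.  This
LTP-on-LTD *veto* is what lets a strong, temporally concentrated LTP signal
suppress the depression that the same depolarization would otherwise cause,
and is the source of the rule's frequency dependence under constant-clamp
stimulation.

Assumptions worth keeping in mind: the rule is local (one synapse, one
voltage), linear in the glutamate trace, and blind to the biophysical origin
of the depolarization — an EPSP, a backpropagating action potential (bAP)
or a dendritic NMDA/calcium spike act only through `u(t)`.  There are no
hard bounds on `w` during induction (a `clip_zero` read-out floor is
available but off by default), and the weight is never fed back into the
dynamics.

## Parameters

| name | meaning | unit | typical range |
|------|---------|------|---------------|
| `tau_x` | glutamate-trace decay | ms | 2–30 |
| `tau_plus` | LTP voltage filter | ms | 2–60 |
| `tau_minus` | LTD voltage filter | ms | 2–60 |
| `theta_plus` | LTP threshold | mV above rest | 8.5–30 |
| `theta_0` | fixed part of LTD threshold | mV above rest | 2.5–15, `< theta_plus` |
| `A_LTP` | LTP amplitude | 1/(mV·ms) | 1e-5–1e-2 |
| `A_LTD` | LTD amplitude | 1/(mV·ms) | 1e-5–1e-2 |
| `b_theta` | veto strength | mV·ms | 0–5e5 |
| `tau_theta` | veto decay | ms | 1–100 |

The "typical range" column is also the default fitting box
(`default_param_bounds()`).  `vbp_preset_params()` ships parameter sets
published for hippocampal CA3 recurrent synapses, neocortical L2/3→L5 and
L5–L5 connections, and two illustrative clamp sets.

## Numerical scheme

All differential equations are integrated by forward Euler with `dt = 0.1`
ms, matching the scheme under which the published parameter values were
obtained — a different integrator would subtly redefine the parameters.
Within one step the order is fixed: the glutamate trace decays and gains
its spike increment; the voltage filters relax toward the step's sample;
the LTP and LTD rates are evaluated with these just-updated traces and the
veto threshold of the *previous* step; the weights accumulate; finally the
veto threshold is updated.  A spike at time `s` belongs to step `n` iff
`t_{n-1} < s <= t_n` (a spike exactly at the trace start belongs to the
first step), so a spike acts in the step in which it arrives.  These
conventions are exposed one step at a time by `plasticity_step()`, and the
compiled integration path (`vbp_simulate()`) is bit-identical to folding
that function over the trace — a property the test suite asserts.

Two independent references validate the integrator before any fitting is
trusted: exact closed forms for the filters on piecewise-constant inputs
and for the LTP accrued by an isolated spike under equilibrated clamp
(`analytic_filter()`, `analytic_single_spike_ltp()`), and an independently
written plain-R loop at `dt = 1e-3` ms with linear trace interpolation
(`fine_grid_reference()`).

A numerical-analysis point that shapes the validation design: forward Euler
at 0.1 ms resolves the filters to a relative accuracy of order
`dt/(2 tau)`.  Where presynaptic activity coincides with unresolved voltage
transients, or where the veto variable is strongly driven (its effective
magnitude `b_theta * A_LTP * x_bar * (u_bar_plus - theta_plus)` can reach
tens of mV with a sub-millisecond effective rise), the scheme is only
first-order accurate and per-protocol errors of a few percent against the
fine grid are expected and observed.  Exact-agreement checks (0.5% level)
are therefore asserted in the resolved regime — spikes arriving after the
filters have equilibrated, veto inactive — while the veto-coupled system is
validated through its convergence order: halving `dt` halves the deviation
from the fine-grid reference.

## Synthetic traces

`trace_synthesis` builds `u(t)` for the protocol families used in
plasticity experiments: constant voltage clamp paired with afferent
stimulation trains, square pulses of height `Δu` and duration `T` with a
single spike before, inside or after the pulse, and pairing protocols that
superpose idealized kernels — a double-exponential EPSP (0.5 ms rise, 10 ms
decay by default), a triangular 2-ms bAP that relaxes onto an exponential
after-depolarization, and a rounded-rectangular plateau standing in for
dendritic NMDA/calcium spikes.  Real dendritic recordings have trial-to-trial
variability, noise, and nonlinear interactions between these components;
the surrogates have none of that, so passing tests demonstrate properties
of the *rule* under controlled inputs, not fidelity to any particular cell.
Trial-type mixtures (e.g. 60 pairings of which one third evoke a dendritic
spike) are simulated per trial type from a fresh state and combined by
repetition-weighted summation — exact when repetitions are far apart
relative to all time constants, which is why protocols below 0.5 Hz default
to this per-trial mode while faster protocols are laid out on one
continuous trace so that residual depolarization can accumulate between
pairings (the mechanism behind frequency-dependent potentiation).

Negative pairing intervals mean the postsynaptic event precedes the
presynaptic spike.

## Fitting

`vbp_fit()` minimizes the squared error
`SE = sum_p (Δw_model,p − Δw_exp,p)^2` over the nine parameters, with both
sides as fractions of the initial weight.  Design choices:

* **Bounds and constraint.** Box bounds as in the table; `theta_plus >
  theta_0` is enforced by a penalty residual plus a post-run repair that
  clips `theta_0` just below `theta_plus`.  Amplitudes are optimized on a
  log10 scale (their box spans three decades).
* **Local search.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  the residual vector.  Any bounded local method would satisfy the
  contract; the multi-start minimum, not the path, is the result.
* **Starts.** A seeded Latin-hypercube design (`generate_initial_points()`),
  amplitudes stratified in log space and the veto strength in square-root
  space (uniform stratification would pile starts into the saturated-veto
  plateau).  By default a larger screened sample (`screen_factor` times
  `n_starts`) is evaluated once and only the best `n_starts` points are
  refined — the scatter-search start selection familiar from global
  optimization toolboxes.
* **Polish and basin hopping.** The best few runs are re-polished with a
  larger iteration budget, and optional deterministic basin-hopping rounds
  perturb the incumbent multiplicatively (up to ~2.5-fold, every third
  round squared) and keep improvements.  The objective is multimodal —
  rectifiers create gradient-free plateaus and near-degenerate valleys
  (e.g. `A_LTP · tau_x` trade-offs) — and cold local searches alone stall
  in decoy minima; hopping from incumbents resolves this reliably on the
  synthetic batteries.  Everything is deterministic given `(data, seed)`.

The default 15-protocol battery (`default_protocol_battery()`) spans five
clamp levels straddling both thresholds, five square-pulse placements
(centered, after-pulse at two delays probing `tau_minus`, pre-pulse at two
lags probing `tau_x`), STDP pairings at ±10 ms and two repetition
frequencies, a burst pairing and a linear/supralinear mixture.  Repetition
counts were chosen so that outcome magnitudes are commensurate (roughly
0.02–0.5 in fractional weight change): with strongly unbalanced outcomes
the squared error is insensitive to the small, timing-informative
protocols and the search finds decoy minima.  The reference ground truth
for self-validation studies (`synthetic_reference_params()`) sits well
inside the box with a deliberately moderate veto (`b_theta = 5e3`), so the
veto is engaged but not saturated; a saturated veto is unidentifiable from
above (any larger value fits equally well).

On noise-free data from this battery the multi-start search recovers the
generating parameters essentially exactly; the two veto parameters are the
weakly identified pair, which is precisely the pattern reported for fits
to experimental recordings, where their across-fold coefficients of
variation exceed 100%.

## Cross-validation and its design choices

`loo_crossval()` refits on all-but-one outcome and scores the held-out
squared error, reporting per-fold results, the median training error
normalized by training-set size, the median test error, and per-parameter
coefficients of variation across folds (population sd over mean, in
percent — the sd convention is not canonical; population sd is used and
labelled).  Two choices deserve a note:

* With nine parameters and (say) seven training outcomes the converged fit
  nearly interpolates, so the normalized training error is expected to fall
  below the test error; observing the reverse is a sign of an
  under-converged fold, which is why the per-fold optimizer budget matters
  more here than anywhere else.
* A `warm_start` option seeds every fold with a full-data fit.  It makes
  the parameter CoV a clean read-out of identifiability, but it leaks the
  held-out outcome into the fold through the start point and visibly
  deflates the test error, so it is **off** by default and in all reported
  studies.

`sensitivity_analysis()` perturbs each parameter by ±5% (one at a time,
18 entries), reporting the change in SE; infeasible `theta_0` perturbations
are clipped and flagged.  `veto_ablation()` refits with `b_theta` fixed at
0 and free, seeding the free fit with the ablated solution so the
nested-model inequality holds by construction.  `voltage_plasticity_curve()`
scans clamp levels (0.5 mV default grid) and reports the no-change/LTD
boundary — which sits at `theta_0` by construction of the rule — and the
LTD→LTP crossover found by linear interpolation between grid levels.
`triplet_prediction()` evaluates pre-post, post-pre and triplet spike
patterns on surrogate kernels; with bAP kernels strong enough to engage
both filters it reproduces the published sign structure (pairs near
no-change or LTD, post-pre-post at 5 ms flipping to LTP through the veto),
and is documented as qualitative: exact percentages depend on the dendritic
voltage model that generated the original traces, which is out of scope.

## Problem sizes used in the shipped studies

The package's own validation studies (test suite and
`scripts/acceptance.R`) use: the 15-protocol default battery for parameter
recovery (25 starts); the 8-protocol compact battery
(`crossval_protocol_battery()`) with outcome noise sd 0.05 and 5 starts per
fold, over 20 replicate noise seeds, for the cross-validation study; 20
random protocols per oracle-equivalence family; and 100-pulse clamp trains
at 2 and 40 Hz for the voltage–plasticity scans.  These sizes were chosen
as the smallest at which the studied effects are comfortably resolved.

## Known limitations

* The rule inherits the identifiability structure of its inputs: protocols
  that never cross `theta_plus` say nothing about the LTP side, and a
  saturated veto bounds `b_theta` only from below.
* Surrogate kernels are idealized; conclusions about real dendrites require
  recorded traces (`read_trace()` ingests two-column delimited text,
  baseline-shifts it so rest = 0, and resamples it to the integration grid).
* Forward Euler at 0.1 ms is part of the model definition here; treating
  `dt` as a free accuracy knob would silently re-scale fitted parameters.
* Multicompartment neuron simulation, calcium dynamics, soft-bounded or
  metaplastic weight rules, and network-level simulation are out of scope.
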