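---
title: "Model-driven design of hERG voltage-clamp protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven design of hERG voltage-clamp protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampdesign)
```

## The problem

hERG (Kv11.1) carries the rapid delayed-rectifier potassium current that
repolarises the cardiac action potential. Mathematical models of its
voltage-dependent gating are calibrated from voltage-clamp recordings, and the
information content of those recordings depends almost entirely on the voltage
protocol applied. Long traditional protocols waste recording time; short
uninformative ones leave parameters unidentifiable and models untested.
`clampdesign` simulates two standard hERG gating models under arbitrary
step/ramp protocols and *synthesises* short, information-rich protocols by
maximising explicit design objectives, under the practical constraints of
automated patch-clamp hardware (at most 64 step/ramp commands per protocol,
voltages rounded to 0.1 mV, durations to 0.1 ms).

## The gating models

Both models are continuous-time Markov chains `dx/dt = A(V) x` whose
transition rates depend exponentially on voltage.

The **four-state model** has states `[C, I, IC, O]` and rates
`k1 = p1*exp(p2*V)`, `k2 = p3*exp(-p4*V)` (activation pathway) and
`k3 = p5*exp(p6*V)`, `k4 = p7*exp(-p8*V)` (inactivation pathway). Because the
two pathways are independent, it is exactly equivalent to a two-gate
Hodgkin-Huxley model: an activation gate `a` with
`da/dt = k1(1-a) - k2 a` and an inactivation (recovery) gate `r` with
`dr/dt = k4(1-r) - k3 r`, with open probability `P(O) = a*r`. The package
exploits this equivalence twice: as a cross-check (the 4-state and 2-gate
solutions must agree to integration tolerance) and as the fast path for the
phase-space coverage objective.

The **five-state model** is a sequential chain `C1-C2-C3-O-I` with six
voltage-dependent rates and a voltage-independent pair `kf`/`kb` between `C2`
and `C3`.

Default parameter values and fit-derived plausibility ranges are shipped both
as built-in defaults (`beattie_parameters()`, `wang_parameters()`,
`*_ranges()`) and as plain-text tables under `inst/extdata/`, stored on the
printed scale with explicit scale factors so that file round-trips are exact.

**Units.** Time is in ms, voltage in mV, rates in ms⁻¹ and conductance in
units of 0.1 µS (the scale the published values are quoted in); the simulated
current `I = g · P(open) · (V − E_rev)` is therefore in 0.1 µS·mV = 0.1 nA.
The model structure itself never fixes the driving force, so the reversal
potential is a configuration value, `e_rev = -88` mV by default (a
room-temperature K⁺ Nernst-style value consistent with the simulated current
shapes); every simulation entry point accepts it as an argument.

## Solvers and numerical choices

Constant-voltage segments are advanced with the exact matrix-exponential
propagator (`x(t+dt) = expm(A dt) x(t)`), which is grid-independent and
bit-deterministic; ramps use adaptive integration (`deSolve::lsoda`,
`rtol = 1e-8`, `atol = 1e-10` by default). Two cross-checking solver routes
are exposed: `method = "adaptive"` integrates everything adaptively and
`method = "reduced"` removes the last state and sets it to one minus the sum
of the others (the usual numerical-stability device for closed Markov
systems); the test suite requires all routes to agree.

Output sampling uses a uniform half-open grid (`t = 0, dt, 2dt, ... <`
duration; a sample falling exactly on a segment boundary belongs to the next
segment), with `dt_out = 1` ms everywhere by default — the same sampling used
by the design objectives, which integrate by rectangle rule on that grid.
Whether objectives should integrate on solver-native steps instead is
genuinely open; uniform 1 ms sampling was chosen because it matches the
sampling used when these protocol families were originally designed, and it
keeps objective evaluations cheap. It is overridable (`dt_out`) throughout.

Initial conditions default to the steady state at the −80 mV holding
potential, obtained by solving `A x = 0`, `sum(x) = 1` directly (with an
explicit failure, not NaN, if the null space is degenerate). During design,
candidate units are always evaluated *with the common head attached*, so each
unit starts from the realistic state history an experiment would produce.

## Protocols

A protocol is an ordered list of step/ramp segments. All designed protocols
share a fixed head (leak ramp at closed-channel voltages, then a +40 mV
activation step provoking a large tail current for conductance estimation;
3400 ms, 7 commands) and tail (a reversal ramp through the expected Nernst
potential, then 390 ms at −120 mV to reset channel state; 2500 ms,
6 commands). With 13 commands reserved, a designed body of 51 steps
(17 three-step units) exactly fills the 64-command hardware budget.

The square-wave family `V(t) = b + Σ aᵢ sign(sin(ωᵢ t + φᵢ))` (with
`sign(0) = 0`) is supported both in closed form and as an exact conversion to
steps whose breakpoints are the union of all component zero-crossings. The
published three-component conversion (amplitudes 54/26/10 mV, frequencies
0.007/0.037/0.19 — printed in ms but clearly angular frequencies in rad/ms,
a units slip we interpret as such — zero phases, offset −30 mV) ships as a
fixture; its body duration is not printed, so the fixture default (600 ms) is
chosen to keep the converted protocol within 64 commands.

The manually-designed protocols of the original staircase family are *not*
reproduced here (their exact step tables are distributed in a separate
supplementary spreadsheet); the package ships a clearly-labelled approximate
`staircase_like_protocol()` whose purpose is self-contained testing, not
fidelity to the original.

## Design objectives

Each designed protocol body is built from `N` units of 3 voltage steps, each
step parameterised by a voltage and a duration. Units are optimised one at a
time, conditional on everything before them (greedy/iterative design; jointly
optimising all steps at once is deliberately out of scope). The objectives:

* **Local sensitivity** (`local_sens`): for unit `i`, maximise
  `∫|∂I/∂pᵢ · pᵢ| dt / Σₖ ∫|∂I/∂pₖ · pₖ| dt`, integrated *only over the
  third step* — the first two steps are free to set up the state.
  Sensitivities use central differences with a 0.1 % relative step; each
  perturbed run re-equilibrates its own initial state, as the physical
  experiment would. Over a shared window the objectives for all parameters
  partition to one.
* **First-order Sobol index** (`sobol`): replace the local index with
  `Var_{pᵢ}(E(I|pᵢ))/Var(I)` under the fit-derived parameter ranges,
  estimated per output time by a Saltelli-type scheme (Latin-hypercube base
  matrices, Jansen estimator) and aggregated by time-averaging over the
  third-step window. The published description gives no explicit time
  aggregation; time-averaging was chosen to mirror the local-sensitivity
  window. The estimator is validated against the closed-form indices of a
  linear test function before use.
* **Sampled-parameter spread** (`brute_rmsd`): draw `M` parameter vectors
  from the ranges and maximise `(2/M²) Σ_{j<k} RMSD(Iⱼ, Iₖ)` over the whole
  three-step window. Draws are log-uniform by default: the ranges span up to
  five orders of magnitude, and uniform draws would never see the lower
  decades (a linear mode is available for comparison).
* **Two-model discrimination** (`discrim`): maximise the RMSD between the
  currents of the two models at their default parameters (a 'local' design
  in parameter space), over the whole unit window. The window choice for
  these two objectives (all three steps rather than only the third) is an
  interpretation — the published text restricts the window explicitly only
  for the local-sensitivity design — and is configurable.
* **Phase-space coverage** (`spacefill`): discretise the `(a, r, V)`
  phase-voltage space `[0,1]×[0,1]×[−120,60]` into 6³ = 216 boxes (half-open
  bins, closed top edge) and maximise the number of *new* boxes the gate
  trajectory visits during the unit at 1 ms sampling. Coverage bookkeeping
  includes the head and tail trajectory: coverage is a property of the full
  applied waveform.

## The optimiser

Each unit is optimised with CMA-ES (implemented in the package; only the
algorithm choice is prescribed by the designs it reproduces), restarted
10 times from uniformly random in-bounds starting points. Box constraints
are enforced by repair: out-of-box candidates are clipped and evaluated at
the feasible point, with the squared repair distance entering the selection
ranking as a penalty (evaluating clipped candidates without any penalty lets
the search mass drift outside the box and stall whenever an optimum sits
near a bound). The initial step size is 1/6 of each bound range, and ties
across restarts are broken by restart index. Designed values are rounded to 0.1 mV / 0.1 ms *before* the final
cross-restart comparison, so the reported score is the score of the shipped
protocol — `score_design()` re-derives every stored unit score from the final
protocol via the public objective functions and must reproduce them exactly.

Gibbs-style variants halve the search dimension by freezing either the three
voltages or the three durations of each unit at uniform draws
(durations ~ U(50, 1000) ms, voltages ~ U(−120, 60) mV; the
randomised-duration discrimination variant draws from U(50, 500) ms) and
optimising the rest, alternating by unit parity in `alternating` mode. For
fully-optimised units the duration bounds default to [50, 1000] ms — the
published designs leave this unstated, and the Gibbs draw range is the
natural default. For the per-parameter objectives the unit count equals the
number of kinetic parameters (8 or 14; whether the conductance should count
as a parameter is ambiguous — the per-parameter objectives here are defined
over kinetic parameters, with `g` includable via `include_conductance` in
the sensitivity machinery).

The nine-parameter square-wave discrimination design
(`squarewave_discrimination_design()`) optimises three amplitudes, three
angular frequencies and three phases (offset fixed at −30 mV) to maximise
two-model RMSD. Its optima tend to sit on the search bounds — ever faster,
larger swings separate the models better — and the function warns when that
happens, since such protocols are likely impractical on real hardware.

## What the synthetic data does and does not emulate

`make_synthetic_current()` adds iid Gaussian noise to a simulated current;
the default test noise (sd 1.5 in current units, i.e. 0.15 nA against ~6 nA
peak currents) is a realistic magnitude for automated patch-clamp wells. It
does **not** emulate series-resistance or leak artefacts, temperature drift,
run-down, or cell-to-cell variability; passing parameter-recovery tests on
this data therefore demonstrates correctness of the simulation/fitting
machinery (absence of an inverse crime), not robustness to real experimental
artefacts. Temperature dependence and drug-binding states are likewise out
of scope: the models are room-temperature parameterisations only.

## Worked example

```{r design, eval = FALSE}
cfg <- design_config(objective = "spacefill", n_units = 17, n_restarts = 10,
                     seed = 1)
runs <- spacefill_design(cfg, n_runs = 5)
runs$metrics          # coverage / two-model RMSD / spread per run
best <- runs$runs[[runs$selection["best_coverage"]]]
write_protocol(best$protocol, "spacefill_best.tsv", hardware = TRUE)
```

At these settings (the problem sizes used throughout the package's own
checks: 17 units, 10 restarts per unit, 5 runs, 1 ms sampling) a single run
optimises 51 steps in about a minute on one core, and the best run typically
covers well over the 126-box benchmark for this design family, out of 216
available boxes.

## Known limitations

* The greedy unit-by-unit designer makes no claim of global optimality over
  all 51 steps.
* The Sobol objective inherits Monte-Carlo noise at small base sample sizes;
  it is deterministic given its seed, but ranking very similar candidate
  units at `n_base` below a few hundred is not meaningful.
* Phase-space coverage is defined through the four-state model's two-gate
  equivalent; it has no direct analogue for the five-state model.
* CMA-ES on the integer-valued coverage objective sees large plateaus;
  restarts matter more than generations there, which is why the designer
  restarts rather than lengthening runs.
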