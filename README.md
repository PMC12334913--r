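# clampdesign

Model-driven design of voltage-clamp protocols for hERG (Kv11.1) channel
kinetics.

Characterising how an ion channel gates means recording its current under a
voltage command `V(t)` and fitting a kinetic model to the result. The quality
of everything downstream — parameter identifiability, model selection, tests
of model assumptions — is set by the protocol, and automated patch platforms
constrain protocols hard (here: at most 64 step/ramp commands). `clampdesign`
is for modellers and electrophysiologists who want short, information-rich
protocols designed *against the models themselves* rather than by hand.

## What it does

* **Simulates** two standard hERG gating models — a four-state Markov model
  `[C, I, IC, O]` with rates `k1 = p1·e^{p2 V}`, `k2 = p3·e^{-p4 V}`,
  `k3 = p5·e^{p6 V}`, `k4 = p7·e^{-p8 V}` (exactly equivalent to a two-gate
  Hodgkin-Huxley model with open probability `a·r`), and a five-state chain
  `C1–C2–C3–O–I` — under arbitrary step/ramp protocols, using an exact
  matrix-exponential propagator on steps and adaptive integration on ramps.
  Current is `I = g · P(open) · (V − E_rev)`.
* **Scores** candidate protocols with the design objectives used for this
  protocol family: normalised local parameter sensitivity
  `∫|∂I/∂pᵢ·pᵢ|dt / Σₖ∫|∂I/∂pₖ·pₖ|dt`, first-order Sobol indices
  `Var_{pᵢ}(E(I|pᵢ))/Var(I)`, sampled-parameter output spread
  `(2/M²)Σ_{j<k} RMSD(Iⱼ, Iₖ)`, two-model discrimination RMSD, and coverage
  of the 6×6×6 box discretisation of the `(a, r, V)` phase-voltage space.
* **Designs** protocols: an iterative 3-step CMA-ES designer (with
  Gibbs-style randomise-one/optimise-the-other variants), multi-run
  space-filling design with three selection criteria, and a nine-parameter
  square-wave discrimination design.
* **Fits** models to (synthetic or real) current traces by sum-of-squares
  CMA-ES on log-parameters, and generates synthetic noisy data for
  self-contained validation.

## Worked example

```r
library(clampdesign)

# simulate the four-state model under a simple activation/tail protocol
sim <- simulate_current(beattie_model(), toy_3step_protocol())
round(range(sim$current), 2)
#> [1]  0.00 51.66          # current in 0.1 nA: ~5 nA peak tail transient
max(abs(rowSums(sim$states) - 1))
#> [1] 1.2e-13              # probability conserved

# design a 17-unit (51-step) space-filling protocol, 5 optimisation runs
cfg  <- design_config(objective = "spacefill", n_units = 17,
                      n_restarts = 10, seed = 1)
runs <- spacefill_design(cfg, n_runs = 5)
runs$metrics
#>   run seed coverage discrim_rmsd   spread
#>   ... per-run boxes visited (of 216), two-model RMSD, sampled spread
max(runs$metrics$coverage)
#> [1] 206                  # best run: 206/216 phase-voltage boxes at 1 ms
best <- runs$runs[[runs$selection[["best_coverage"]]]]
n_commands(best$protocol)
#> [1] 64                   # 7 head + 51 designed + 6 tail commands
write_protocol(best$protocol, "spacefill_best.tsv", hardware = TRUE)
```

The coverage number is the count of distinct boxes the model's
activation/inactivation/voltage trajectory enters: more boxes means the
protocol pushes the model through more of its qualitatively distinct
behaviours per second of recording. Designs of this family are expected to
visit at least ~126 of the 216 boxes; results are stochastic in the seed.

The methods vignette (`vignettes/protocol-design.Rmd`) documents the models,
units, objectives, optimiser settings and the package's numerical and design
choices in detail.

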