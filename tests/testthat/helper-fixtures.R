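# Shared small fixtures; everything is generated in code.
beattie <- beattie_model()
wang <- wang_model()

# A short context for objective tests: cheap but non-trivial state history.
short_context <- clamp_protocol(list(step_segment(200, -80),
                                     step_segment(300, 20)),
                                name = "short_context")

random_unit <- function(seed) {
  set.seed(seed)
  design_unit(runif(3, -120, 60), runif(3, 50, 600))
}

# Random positive perturbations of the default kinetic parameters.
perturbed_params <- function(params, seed, sd = 0.3) {
  set.seed(seed)
  params$values <- params$values * exp(rnorm(length(params$values), 0, sd))
  params
}
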