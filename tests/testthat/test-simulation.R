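test_that("a steady-state start under constant voltage stays fixed", {
  for (mdl in list(beattie, wang)) {
    prot <- clamp_protocol(list(step_segment(1000, -50)))
    sim <- simulate_current(mdl, prot, x0 = steady_state(mdl, -50))
    expect_lt(max(abs(sweep(sim$states, 2, sim$states[1, ]))), 1e-9)
  }
})

test_that("probability is conserved on all fixture protocols", {
  fx <- fixture_protocols()
  for (nm in names(fx)) {
    for (mdl in list(beattie, wang)) {
      sim <- simulate_current(mdl, fx[[nm]])
      expect_lt(max(abs(rowSums(sim$states) - 1)), 1e-8)
      expect_true(all(sim$open_prob >= -1e-10 & sim$open_prob <= 1 + 1e-10))
    }
  }
})

test_that("propagator and adaptive solvers agree on the common head", {
  for (mdl in list(beattie, wang)) {
    s1 <- simulate_current(mdl, common_head(), method = "propagator")
    s2 <- simulate_current(mdl, common_head(), method = "adaptive")
    expect_lt(max(abs(s1$states - s2$states)), 1e-6)
  }
})

test_that("eliminating one state ('one minus the sum of the rest') is consistent", {
  for (mdl in list(beattie, wang)) {
    sr <- simulate_current(mdl, toy_3step_protocol(), method = "reduced",
                           rtol = 1e-11, atol = 1e-13)
    sf <- simulate_current(mdl, toy_3step_protocol(), method = "adaptive",
                           rtol = 1e-11, atol = 1e-13)
    expect_lt(max(abs(sr$states - sf$states)), 1e-8)
  }
})

test_that("the current shows the hERG signature: large tail on repolarisation", {
  sim <- simulate_current(beattie, toy_3step_protocol())
  bounds <- cumsum(c(0, toy_3step_protocol()$segments$duration))
  at_plus40 <- sim$times >= bounds[2] & sim$times < bounds[3]
  at_minus40 <- sim$times >= bounds[3]
  expect_gt(max(abs(sim$current[at_minus40])),
            mean(abs(sim$current[at_plus40])))
})

test_that("the propagator is deterministic and grid-independent at segment ends", {
  s1 <- simulate_current(beattie, toy_3step_protocol(), dt_out = 1)
  s2 <- simulate_current(beattie, toy_3step_protocol(), dt_out = 1)
  expect_identical(s1$states, s2$states)
  half <- simulate_current(beattie, toy_3step_protocol(), dt_out = 0.5)
  expect_lt(max(abs(s1$final_state - half$final_state)), 1e-12)
})

test_that("bad initial conditions and out-of-grid observations fail loudly", {
  expect_error(simulate_current(beattie, toy_3step_protocol(), x0 = c(1, 0, 0)),
               "length 4")
  expect_error(simulate_current(beattie, toy_3step_protocol(),
                                x0 = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("rmsd is a symmetric root-mean-square with hand-checkable values", {
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(rmsd(x, y), rmsd(y, x))
  expect_equal(rmsd(x, x), 0)
  expect_error(rmsd(x, y[-1]), "mismatch")
})
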