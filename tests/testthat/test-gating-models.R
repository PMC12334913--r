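test_that("rate laws reproduce published values at V = 0 and obey the exponential law", {
  k <- beattie_rates(0)
  expect_equal(k[["k1"]], 1.68e-4)  # equals p1 at V = 0
  expect_equal(k[["k2"]], 4.34e-5)  # equals p3 at V = 0
  r <- wang_rates(0)
  expect_equal(r[["a1"]], 1.24e-1)  # equals q1 at V = 0
  expect_equal(r[["kf"]], 1.31e-2)
  expect_equal(wang_rates(57)[["kf"]], 1.31e-2)  # voltage-independent

  # exponential law identity: k1(V + d)/k1(V) = exp(p2 * d)
  p <- perturbed_params(beattie_parameters(), 1)
  d <- 13.7
  for (V in c(-90, 0, 42)) {
    expect_equal(beattie_rates(V + d, p)[["k1"]] / beattie_rates(V, p)[["k1"]],
                 exp(p$values[["p2"]] * d))
  }
  # symmetric exponential product: ba0(V) * ba0(-V) = q11^2
  q <- wang_parameters()
  for (V in c(-77, 13, 60))
    expect_equal(wang_rates(V, q)[["ba0"]] * wang_rates(-V, q)[["ba0"]],
                 q$values[["q11"]]^2)
  expect_error(beattie_rates(NaN), "finite")
  expect_error(wang_rates(Inf), "finite")
})

test_that("rates are monotone in voltage as per the model structure arrows", {
  V <- seq(-120, 60, length.out = 100)
  kb <- beattie_rates(V)
  for (up in c("k1", "k3")) expect_true(all(diff(kb[, up]) > 0))
  for (dn in c("k2", "k4")) expect_true(all(diff(kb[, dn]) < 0))
  kw <- wang_rates(V)
  for (up in c("a1", "aa0", "aa1")) expect_true(all(diff(kw[, up]) > 0))
  for (dn in c("ba1", "b1", "ba0")) expect_true(all(diff(kw[, dn]) < 0))
  for (cst in c("kf", "kb")) expect_true(all(diff(kw[, cst]) == 0))
})

test_that("transition matrices have the printed sparsity and conserve probability", {
  A <- transition_matrix(beattie, -17)
  k <- beattie_rates(-17)
  expect_equal(A["O", "C"], k[["k1"]])
  expect_equal(A["C", "O"], k[["k2"]])
  expect_equal(A["C", "IC"], k[["k4"]])
  expect_equal(A["I", "IC"], k[["k1"]])
  expect_equal(unname(A["C", "I"]), 0)
  expect_equal(unname(A["O", "IC"]), 0)

  W <- transition_matrix(wang, 23)
  expect_equal(W["C3", "C2"], wang_parameters()$values[["kf"]])
  expect_equal(W["C2", "C3"], wang_parameters()$values[["kb"]])
  expect_identical(W["C3", "C2"], transition_matrix(wang, -80)["C3", "C2"])
  expect_equal(unname(W["C1", "C3"]), 0)
  expect_equal(unname(W["O", "I"]), wang_rates(23)[["b1"]])

  # conservation: 1' A = 0 over random voltage/parameter draws
  set.seed(99)
  for (i in 1:1000) {
    V <- runif(1, -120, 60)
    mdl <- if (i %% 2) beattie_model(perturbed_params(beattie_parameters(), i))
           else wang_model(perturbed_params(wang_parameters(), i))
    A <- transition_matrix(mdl, V)
    expect_lt(max(abs(colSums(A))), 1e-12 * max(1, max(abs(A))))
  }
})

test_that("steady state is a normalised null-space vector matching the long-time ODE limit", {
  for (mdl in list(beattie, wang)) {
    for (V in c(-80, -40, 20)) {
      ss <- steady_state(mdl, V)
      expect_equal(sum(ss), 1)
      expect_true(all(ss >= 0))
      A <- transition_matrix(mdl, V)
      expect_lt(max(abs(A %*% ss)), 1e-12)
    }
  }
  # oracle: adaptive ODE integration for 1e5 ms from an interior start
  A <- transition_matrix(beattie, -80)
  sol <- deSolve::lsoda(rep(0.25, 4), c(0, 1e5),
                        function(t, y, p) list(as.numeric(A %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[2, -1] - steady_state(beattie, -80))), 1e-6)
})

test_that("the four-state steady state factorises into the two HH gate steady states", {
  for (V in c(-80, -30, 40)) {
    ss <- steady_state(beattie, V)
    gi <- hh_gate_inf(V)
    expect_equal(ss[["O"]], gi$a_inf * gi$r_inf, tolerance = 1e-8)
    expect_equal(ss[["C"]], (1 - gi$a_inf) * gi$r_inf, tolerance = 1e-8)
    expect_equal(ss[["I"]], gi$a_inf * (1 - gi$r_inf), tolerance = 1e-8)
    expect_equal(ss[["IC"]], (1 - gi$a_inf) * (1 - gi$r_inf), tolerance = 1e-8)
  }
})
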