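test_that("the phase grid discretisation and binning match a per-point oracle", {
  g <- phase_grid()
  expect_equal(g$n_boxes, 216)
  # brute-force loop oracle over random points, including exact bounds
  set.seed(10)
  n <- 1000
  a <- c(runif(n - 4), 0, 1, 0.5, 1)
  r <- c(runif(n - 4), 1, 0, 0.5, 1)
  v <- c(runif(n - 4, -120, 60), -120, 60, 0, 60)
  loop_boxes <- integer(0)
  for (i in seq_len(n)) {
    ia <- min(max(floor(a[i] * 6), 0), 5)
    ir <- min(max(floor(r[i] * 6), 0), 5)
    iv <- min(max(floor((v[i] + 120) / 180 * 6), 0), 5)
    loop_boxes <- union(loop_boxes, ia + 6 * ir + 36 * iv + 1)
  }
  cov <- phase_coverage(data.frame(a = a, r = r, v = v), g)
  expect_setequal(cov$boxes, loop_boxes)
  expect_equal(cov$new_boxes, length(loop_boxes))
})

test_that("coverage counts only new boxes and clamps stray samples", {
  g <- phase_grid()
  const <- data.frame(a = rep(0.5, 10), r = 0.5, v = 0)
  cov <- phase_coverage(const, g)
  expect_equal(cov$new_boxes, 1)
  cov2 <- phase_coverage(const, g, already_visited = cov$visited)
  expect_equal(cov2$new_boxes, 0)
  expect_warning(phase_coverage(data.frame(a = 1.5, r = 0.5, v = 0), g),
                 "clamped")
})

test_that("the pairwise-RMSD spread matches hand-evaluated cases", {
  # three constant traces 0, 1, 2: (2/9) * (1 + 2 + 1) = 8/9
  traces <- matrix(rep(c(0, 1, 2), each = 5), nrow = 3, byrow = TRUE)
  expect_equal(pairwise_rmsd_spread(traces), 8 / 9)
  # M = 2: RMSD / 2
  two <- matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE)
  expect_equal(pairwise_rmsd_spread(two), sqrt(12.5) / 2)
  # identical traces: 0; permutation invariance
  same <- matrix(1.7, 4, 6)
  expect_equal(pairwise_rmsd_spread(same), 0)
  set.seed(3)
  m <- matrix(rnorm(24), 4, 6)
  expect_equal(pairwise_rmsd_spread(m), pairwise_rmsd_spread(m[c(3, 1, 4, 2), ]))
  expect_error(pairwise_rmsd_spread(m[1, , drop = FALSE]), "M = 2")
})

test_that("local-sensitivity objectives partition to one over a shared window", {
  unit <- random_unit(21)
  s <- vapply(1:8, local_sensitivity_objective, numeric(1), unit = unit,
              context = short_context, model = beattie, dt_out = 5)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(sum(s), 1, tolerance = 1e-9)
})

test_that("an inactivation-rate parameter scores higher on an active unit than a closed one", {
  closed <- design_unit(c(-120, -120, -120), c(300, 300, 300))
  active <- design_unit(c(40, -40, -40), c(300, 300, 300))
  i_p7 <- 7
  s_closed <- local_sensitivity_objective(i_p7, closed, short_context, beattie,
                                          dt_out = 5)
  s_active <- local_sensitivity_objective(i_p7, active, short_context, beattie,
                                          dt_out = 5)
  expect_lte(as.numeric(s_closed), as.numeric(s_active))
})

test_that("model discrimination is symmetric, zero for identical models, and prefers flicker", {
  unit <- design_unit(c(40, -120, 40), c(100, 100, 100))
  expect_equal(model_discrimination_objective(unit, short_context, beattie,
                                              beattie, dt_out = 5), 0)
  ab <- model_discrimination_objective(unit, short_context, beattie, wang,
                                       dt_out = 5)
  ba <- model_discrimination_objective(unit, short_context, wang, beattie,
                                       dt_out = 5)
  expect_equal(ab, ba)
  hold <- design_unit(c(-80, -80, -80), c(100, 100, 100))
  expect_gt(ab, model_discrimination_objective(hold, short_context, beattie,
                                               wang, dt_out = 5))
})

test_that("the sampled-parameter spread objective is positive and permutation-stable", {
  samples <- sample_parameters(beattie_ranges(), 4, seed = 5)
  unit <- design_unit(c(20, -50, 0), c(100, 150, 100))
  val <- brute_force_spread_objective(unit, short_context, beattie, samples,
                                      dt_out = 5)
  expect_gt(val, 0)
  perm <- samples
  perm$samples <- perm$samples[c(3, 1, 4, 2), ]
  expect_equal(brute_force_spread_objective(unit, short_context, beattie,
                                            perm, dt_out = 5), val)
  one <- samples
  one$samples <- one$samples[1, , drop = FALSE]
  expect_error(brute_force_spread_objective(unit, short_context, beattie,
                                            one, dt_out = 5), "M = 2")
})

test_that("parameter samples respect their bounds on both draw scales", {
  for (sc in c("log", "linear")) {
    s <- sample_parameters(wang_ranges(), 50, scale = sc, seed = 2)
    expect_true(all(sweep(s$samples, 2, wang_ranges()$lower, ">=")))
    expect_true(all(sweep(s$samples, 2, wang_ranges()$upper, "<=")))
  }
  s1 <- sample_parameters(beattie_ranges(), 10, seed = 7)
  s2 <- sample_parameters(beattie_ranges(), 10, seed = 7)
  expect_identical(s1$samples, s2$samples)
})

test_that("the objective registry exposes the five design objectives", {
  expect_setequal(list_objectives(),
                  c("local_sens", "sobol", "brute_rmsd", "discrim",
                    "spacefill"))
  expect_identical(get_objective("spacefill"), phase_coverage_objective)
  expect_error(get_objective("nope"), "unknown objective")
})
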