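test_that("CMA-ES recovers the maximiser of a smooth toy objective within the rounding grid", {
  target <- c(-31.4, 12.7, 55.1, 222.2, 87.3, 641.8)
  cfg <- design_config("spacefill", n_restarts = 2L, seed = 4,
                       cma = list(maxiter = 200))
  set.seed(4)
  unit <- optimise_unit(function(u) {
    x <- c(u$v, u$dt)
    -sum(((x - target) / c(180, 180, 180, 950, 950, 950))^2)
  }, cfg)
  expect_lt(max(abs(unit$v - target[1:3])), 0.1 + 1e-9)
  expect_lt(max(abs(unit$dt - target[4:6])), 0.5)
  # rounded to the practical grid
  expect_equal(unit$v, round(unit$v, 1))
  expect_equal(unit$dt, round(unit$dt, 1))
})

test_that("a constant objective yields an in-bounds unit without crashing", {
  cfg <- design_config("spacefill", n_restarts = 1L, seed = 9,
                       cma = list(maxiter = 3))
  set.seed(9)
  unit <- optimise_unit(function(u) 1, cfg)
  expect_true(all(unit$v >= -120 & unit$v <= 60))
  expect_true(all(unit$dt >= 50 & unit$dt <= 1000))
  expect_equal(attr(unit, "score"), 1)
})

test_that("frozen scalars pass through the optimiser untouched", {
  cfg <- design_config("spacefill", n_restarts = 1L, seed = 2,
                       cma = list(maxiter = 3))
  frozen <- list(v = rep(NA_real_, 3), dt = c(123.456, 234.567, 345.678),
                 free_mask = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  set.seed(2)
  unit <- optimise_unit(function(u) sum(u$v), cfg, frozen = frozen)
  expect_identical(unit$dt, frozen$dt)  # exact, not rounded
  expect_equal(unit$v, round(unit$v, 1))
})

test_that("iterative designs are reproducible and respect Gibbs masks", {
  cfg <- design_config("spacefill", n_units = 4L, n_restarts = 1L, seed = 8,
                       gibbs_mode = "alternating", cma = list(maxiter = 10))
  r1 <- iterative_design(cfg)
  r2 <- iterative_design(cfg)
  expect_identical(r1$protocol$segments, r2$protocol$segments)
  expect_identical(r1$unit_scores, r2$unit_scores)
  # odd units freeze durations (draws in [50, 1000]); even units freeze voltages
  expect_identical(r1$units[[1]]$free_mask, c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_identical(r1$units[[2]]$free_mask, c(rep(FALSE, 3), rep(TRUE, 3)))
  for (i in c(1, 3)) {
    expect_true(all(r1$units[[i]]$dt >= 50 & r1$units[[i]]$dt <= 1000))
    # frozen draws are continuous, optimised voltages sit on the 0.1 grid
    expect_equal(r1$units[[i]]$v, round(r1$units[[i]]$v, 1))
  }
  for (i in c(2, 4))
    expect_true(all(r1$units[[i]]$v >= -120 & r1$units[[i]]$v <= 60))
})

test_that("unit accounting: 17 units give a 51-step body and 64 total commands", {
  cfg <- design_config("spacefill", n_units = 17L, n_restarts = 1L, seed = 13,
                       cma = list(maxiter = 2))
  res <- iterative_design(cfg)
  expect_equal(n_commands(res$body), 51)
  expect_equal(n_commands(res$protocol), 64)
  expect_silent(validate_protocol(res$protocol, hardware = TRUE))
})

test_that("stored unit scores equal re-evaluation on the final protocol", {
  for (obj in c("spacefill", "discrim")) {
    cfg <- design_config(obj, n_units = 2L, n_restarts = 1L, seed = 5,
                         cma = list(maxiter = 8))
    res <- iterative_design(cfg)
    expect_equal(score_design(res), res$unit_scores, tolerance = 1e-12)
  }
  cfg <- design_config("brute_rmsd", n_units = 2L, n_restarts = 1L, seed = 5,
                       M = 4L, cma = list(maxiter = 4))
  res <- iterative_design(cfg)
  expect_equal(score_design(res), res$unit_scores, tolerance = 1e-12)
})

test_that("cumulative space-fill coverage is consistent with per-unit scores", {
  cfg <- design_config("spacefill", n_units = 3L, n_restarts = 1L, seed = 6,
                       cma = list(maxiter = 10))
  res <- iterative_design(cfg)
  head_boxes <- length(phase_coverage(hh_trajectory(common_head()))$visited)
  body_cov <- protocol_phase_coverage(concat_protocols(common_head(),
                                                       res$body))
  expect_equal(body_cov, head_boxes + sum(res$unit_scores))
  expect_true(all(res$unit_scores >= 0))
})

test_that("space-fill run selection ranks runs under three criteria", {
  cfg <- design_config("spacefill", n_units = 2L, n_restarts = 1L, seed = 31,
                       M = 3L, cma = list(maxiter = 5))
  sf <- spacefill_design(cfg, n_runs = 2L)
  expect_equal(nrow(sf$metrics), 2)
  expect_true(all(sf$metrics$coverage <= 216))
  expect_true(all(sf$selection %in% 1:2))
  expect_equal(unname(sf$selection["best_coverage"]),
               which.max(sf$metrics$coverage))
})

test_that("square-wave discrimination design is self-consistent and flags bound-hitting", {
  # identical models: objective is zero everywhere
  same <- suppressWarnings(squarewave_discrimination_design(
    beattie, beattie, duration = 200, n_restarts = 1, maxiter = 2, seed = 1))
  expect_equal(same$score, 0)
  # tight bounds force the optimum onto the boundary: the warning must fire
  expect_warning(
    sw <- squarewave_discrimination_design(beattie, wang, duration = 300,
                                           amp_bounds = c(0.5, 5),
                                           omega_bounds = c(0.005, 0.05),
                                           n_restarts = 1, maxiter = 8,
                                           seed = 2),
    "bounds")
  expect_true(sw$boundary_hit)
  # returned score equals the RMSD of the two currents recomputed from scratch
  body <- square_wave_to_segments(sw$spec, 300, max_segments = 100000L)
  full <- wrap_with_common(body)
  sa <- simulate_current(beattie, full)
  sb <- simulate_current(wang, full)
  win <- sa$times >= 3400 & sa$times < 3700
  expect_equal(rmsd(sa$current[win], sb$current[win]), sw$score,
               tolerance = 1e-10)
  expect_equal(sw$spec$b, -30)
})
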