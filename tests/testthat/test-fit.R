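test_that("synthetic currents are noise-free at sd 0 and seed-reproducible", {
  syn0 <- make_synthetic_current(beattie, toy_3step_protocol(), noise_sd = 0,
                                 seed = 1)
  expect_identical(syn0$observed, syn0$true_current)
  s1 <- make_synthetic_current(beattie, toy_3step_protocol(), noise_sd = 2,
                               seed = 42)
  s2 <- make_synthetic_current(beattie, toy_3step_protocol(), noise_sd = 2,
                               seed = 42)
  expect_identical(s1$observed, s2$observed)
  expect_error(make_synthetic_current(beattie, toy_3step_protocol(),
                                      noise_sd = -1), ">= 0")
})

test_that("added noise has the requested variance (law of large numbers)", {
  syn <- make_synthetic_current(beattie, staircase_like_protocol(),
                                noise_sd = 2, seed = 7, dt_out = 1)
  expect_gte(length(syn$times), 1e4)
  v <- stats::var(syn$observed - syn$true_current)
  expect_lt(abs(v - 4) / 4, 0.1)
})

test_that("a conductance-only fit to a doubled trace returns exactly twice g", {
  syn <- make_synthetic_current(beattie, toy_3step_protocol(), dt_out = 5)
  fit <- fit_model(beattie, toy_3step_protocol(), 2 * syn$observed,
                   fixed_kinetics = TRUE, dt_out = 5)
  expect_equal(coef(fit)[["g"]], 2 * beattie$params$g, tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("fitting the wrong model family leaves a larger residual", {
  syn <- make_synthetic_current(beattie, toy_3step_protocol(), dt_out = 5)
  own <- fit_model(beattie, toy_3step_protocol(), syn$observed, seed = 2,
                   maxiter = 300, dt_out = 5)
  cross <- fit_model(wang, toy_3step_protocol(), syn$observed, seed = 2,
                     maxiter = 300, dt_out = 5)
  expect_gt(cross$rmsd, own$rmsd)
})

test_that("fit objects expose the standard accessor methods", {
  syn <- make_synthetic_current(beattie, toy_3step_protocol(), dt_out = 5)
  fit <- fit_model(beattie, toy_3step_protocol(), syn$observed,
                   fixed_kinetics = TRUE, dt_out = 5)
  expect_named(coef(fit), c(paste0("p", 1:8), "g"))
  expect_length(residuals(fit), length(syn$observed))
  expect_equal(fitted(fit) + residuals(fit), syn$observed)
  pred <- predict(fit, protocol = common_head())
  expect_s3_class(pred, "clamp_simulation")
  expect_output(print(fit), "RMSD")
  expect_error(fit_model(beattie, toy_3step_protocol(), syn$observed[-1]),
               "samples")
})
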