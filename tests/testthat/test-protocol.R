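test_that("the common head and tail reproduce the published clamp sections", {
  h <- common_head()
  expect_equal(n_commands(h), 7)
  expect_equal(protocol_duration(h), 3400)
  expect_equal(h$segments$duration, c(250, 50, 400, 200, 1000, 500, 1000))
  expect_equal(h$segments$kind[3], "ramp")
  expect_equal(h$segments$v_start[3], -120)
  expect_equal(h$segments$v_end[3], -80)
  expect_equal(h$segments$v_start[5], 40)

  t <- common_tail()
  expect_equal(n_commands(t), 6)
  expect_equal(protocol_duration(t), 2500)
  expect_equal(sum(t$segments$kind == "ramp"), 1)
  expect_equal(t$segments$duration[4], 100)
  expect_equal(t$segments$v_end[4], -110)

  body <- toy_3step_protocol()
  expect_equal(n_commands(wrap_with_common(body)), 13 + n_commands(body))
})

test_that("voltage lookup is half-open with linear ramps", {
  h <- common_head()
  # midpoint of the 400 ms leak ramp (-120 -> -80) at t = 500 ms
  expect_equal(voltage_at(h, 500), -100)
  # inside a step: constant
  expect_equal(voltage_at(h, c(251, 260.5, 299.9)), c(-120, -120, -120))
  # exact boundary belongs to the next segment
  expect_equal(voltage_at(h, 250), -120)
  expect_equal(voltage_at(h, 300), -120)  # ramp start value
  expect_equal(voltage_at(h, 700), -80)
  expect_error(voltage_at(h, 3400), "out of range")
  expect_error(voltage_at(h, -1), "out of range")
})

test_that("half-open segment grids partition the output grid without double counting", {
  h <- wrap_with_common(toy_3step_protocol())
  sim <- simulate_current(beattie, h, dt_out = 1)
  expect_equal(length(sim$times), protocol_duration(h))
  expect_false(any(duplicated(sim$times)))
})

test_that("protocol files round-trip losslessly and malformed rows are reported", {
  path <- file.path(tempdir(), "head.tsv")
  write_protocol(common_head(), path)
  back <- read_protocol(path)
  expect_equal(back$segments, common_head()$segments)

  # designed-resolution values survive
  p <- clamp_protocol(list(step_segment(123.4, -56.7),
                           ramp_segment(0.1, -120, 59.9)))
  write_protocol(p, path)
  expect_equal(read_protocol(path)$segments, p$segments)

  writeLines(c("kind\tduration_ms\tv_start_mV\tv_end_mV",
               "step\t100\t-80\t-80",
               "step\t-5\t-80\t-80"), path)
  expect_error(read_protocol(path), "row 2")
  writeLines(c("kind\tduration_ms\tv_start_mV\tv_end_mV",
               "step\t100\t-80\t-70"), path)
  expect_error(read_protocol(path), "v_start != v_end")
})

test_that("hardware export refuses protocols exceeding 64 commands", {
  many <- clamp_protocol(data.frame(kind = "step", duration = rep(10, 65),
                                    v_start = -80, v_end = -80))
  expect_error(validate_protocol(many, hardware = TRUE), "64")
  expect_error(write_protocol(many, tempfile(), hardware = TRUE), "64")
  ok <- clamp_protocol(data.frame(kind = "step", duration = rep(10, 64),
                                  v_start = -80, v_end = -80))
  expect_silent(validate_protocol(ok, hardware = TRUE))
})

test_that("step segments with unequal endpoint voltages are rejected", {
  expect_error(clamp_protocol(data.frame(kind = "step", duration = 10,
                                         v_start = -80, v_end = -70)),
               "v_start != v_end")
  expect_error(step_segment(0, -80), "positive")
})
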