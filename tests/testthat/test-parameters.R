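test_that("default parameter sets carry the published values on natural scale", {
  p <- beattie_parameters()
  expect_equal(p$values[["p1"]], 1.68e-4)
  expect_equal(p$values[["p3"]], 4.34e-5)
  expect_equal(p$g, 2.44)
  expect_length(p$values, 8)

  q <- wang_parameters()
  expect_equal(q$values[["q1"]], 1.24e-1)
  expect_equal(q$values[["kf"]], 1.31e-2)
  expect_equal(q$values[["kb"]], 0.67e-2)
  expect_length(q$values, 14)
  expect_equal(q$g, 2.11)
})

test_that("parameter ranges are ordered, positive and aligned", {
  for (r in list(beattie_ranges(), wang_ranges())) {
    expect_true(all(r$lower > 0))
    expect_true(all(r$lower <= r$upper))
    expect_identical(names(r$lower), names(r$upper))
  }
  expect_equal(wang_ranges()$upper[["kb"]], 99993e-2)
})

test_that("constructor rejects invalid parameter sets", {
  expect_error(kinetic_parameters(c(a = 1, a = 2), g = 1), "unique")
  expect_error(kinetic_parameters(c(a = 1, b = -2), g = 1), "positive")
  expect_error(kinetic_parameters(c(a = 1), g = 0), "positive")
  expect_error(parameter_ranges(c(a = 2), c(a = 1)), "<=")
})

test_that("shipped parameter tables round-trip the published table exactly", {
  for (mod in c("beattie", "wang")) {
    path <- file.path(tempdir(), paste0(mod, ".tsv"))
    write_parameter_table(default_parameter_table(mod), path)
    back <- read_parameter_table(path)
    ref_p <- if (mod == "beattie") beattie_parameters() else wang_parameters()
    ref_r <- if (mod == "beattie") beattie_ranges() else wang_ranges()
    expect_identical(back$parameters$values, ref_p$values)
    expect_identical(back$parameters$g, ref_p$g)
    expect_identical(back$ranges$lower, ref_r$lower)
    expect_identical(back$ranges$upper, ref_r$upper)
  }
  shipped <- system.file("extdata", "beattie_parameters.tsv",
                         package = "clampdesign")
  expect_identical(read_parameter_table(shipped)$parameters$values,
                   beattie_parameters()$values)
})
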