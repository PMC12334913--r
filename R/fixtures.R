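#' Approximate staircase-like test protocol
#'
#' A synthetic stand-in for the manually-designed staircase protocol family:
#' an ascending then descending sequence of 500 ms steps with interleaved
#' deactivating dips, exercising activation, inactivation and tail currents.
#' It is *not* the published staircase protocol (whose exact step table is
#' distributed separately); it is a clearly-labelled approximation for
#' self-contained testing.
#'
#' @param wrap add the common head and tail sections.
#' @return a [clamp_protocol()].
#' @export
staircase_like_protocol <- function(wrap = FALSE) {
  up <- seq(-60, 40, by = 20)
  down <- seq(20, -80, by = -20)
  segs <- list()
  for (v in up) {
    segs <- c(segs, list(step_segment(500, v), step_segment(500, v - 40)))
  }
  for (v in down) {
    segs <- c(segs, list(step_segment(500, v), step_segment(500, v - 40)))
  }
  segs <- c(segs, list(step_segment(500, -120)))
  body <- clamp_protocol(segs, name = "staircase_like")
  if (wrap) wrap_with_common(body, name = "staircase_like_full") else body
}

#' A minimal three-step test protocol
#'
#' Holding, activation, and repolarisation steps provoking the
#' characteristic hERG tail current; handy as a cheap unit-test fixture.
#'
#' @return a [clamp_protocol()].
#' @export
toy_3step_protocol <- function() {
  clamp_protocol(list(step_segment(500, -80),
                      step_segment(1000, 40),
                      step_segment(500, -40)),
                 name = "toy_3step")
}

#' The published square-wave protocol fixture
#'
#' The three-component square-wave conversion ([squarewave_paper_spec()])
#' rendered as a step protocol.  The published description does not state
#' the body duration; the default (600 ms) is chosen so that the converted
#' protocol stays within the 64-command hardware limit once the common head
#' and tail are added.
#'
#' @param duration body duration in ms.
#' @param wrap add the common head and tail.
#' @return a [clamp_protocol()].
#' @export
squarewave_protocol <- function(duration = 600, wrap = FALSE) {
  body <- square_wave_to_segments(squarewave_paper_spec(), duration,
                                  name = "squarewave")
  if (wrap) wrap_with_common(body, name = "squarewave_full") else body
}

#' Named set of fixture protocols
#'
#' All fixtures are generated in code (bit-identically reproducible, no
#' network access): the common head and tail, the published square-wave
#' conversion, the approximate staircase-like protocol and a toy three-step
#' protocol.
#'
#' @return named list of [clamp_protocol()] objects.
#' @export
fixture_protocols <- function() {
  list(table2_head = common_head(),
       table2_tail = common_tail(),
       squarewave_paper = squarewave_protocol(),
       staircase_like = staircase_like_protocol(),
       toy_3step = toy_3step_protocol())
}

#' Generate a synthetic current recording
#'
#' Simulates a model under a protocol and adds iid Gaussian noise:
#' `I_obs(t) = I_true(t) + N(0, noise_sd^2)`.  The ground-truth parameters
#' and seed are stored alongside, so parameter-recovery tests are
#' self-contained.
#'
#' @inheritParams simulate_current
#' @param noise_sd noise standard deviation (same units as the current,
#'   0.1 nA); >= 0.
#' @param seed RNG seed.
#' @return an object of class `synthetic_current`: list with `times`,
#'   `observed`, `true_current`, `protocol`, `model`, `params`, `noise_sd`,
#'   `seed`, `dt_out`.
#' @export
make_synthetic_current <- function(model, protocol, noise_sd = 0, seed = 1L,
                                   dt_out = 1, e_rev = -88) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  sim <- simulate_current(model, protocol, dt_out = dt_out, e_rev = e_rev)
  set.seed(seed)
  noise <- if (noise_sd > 0)
    stats::rnorm(length(sim$current), 0, noise_sd) else 0
  structure(list(times = sim$times, observed = sim$current + noise,
                 true_current = sim$current, protocol = protocol,
                 model = model$name, params = model$params,
                 noise_sd = noise_sd, seed = seed, dt_out = dt_out,
                 e_rev = e_rev),
            class = "synthetic_current")
}

#' @export
print.synthetic_current <- function(x, ...) {
  cat("Synthetic current: model '", x$model, "', protocol '",
      x$protocol$name, "', ", length(x$times), " samples, noise sd = ",
      x$noise_sd, "\n", sep = "")
  invisible(x)
}
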