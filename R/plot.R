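#' Plot a voltage-clamp protocol
#'
#' Draws the command voltage `V(t)` as a line trace.
#'
#' @param x a [clamp_protocol()].
#' @param dt plotting resolution (ms).
#' @param ... passed to [graphics::plot()].
#' @export
plot.clamp_protocol <- function(x, dt = 1, ...) {
  t <- .grid_times(0, protocol_duration(x), dt)
  graphics::plot(t, voltage_at(x, t), type = "l", xlab = "time (ms)",
                 ylab = "voltage (mV)", main = x$name, ...)
  invisible(x)
}

#' Plot a simulation: protocol above, current below
#'
#' @param x a [simulate_current()] result.
#' @param ... passed to the current panel.
#' @export
plot.clamp_simulation <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$times, x$voltages, type = "l", xlab = "time (ms)",
                 ylab = "voltage (mV)", main = paste(x$model, "/", x$protocol))
  graphics::plot(x$times, x$current, type = "l", xlab = "time (ms)",
                 ylab = "current (0.1 nA)", ...)
  invisible(x)
}

#' Plot a protocol with simulated currents from one or more models
#'
#' Mirrors the usual presentation of designed protocols: the voltage
#' command on top, model currents below.
#'
#' @param protocol a [clamp_protocol()].
#' @param models list of [gating_model()]s.
#' @param file optional path; when given, a PNG is written there.
#' @param dt_out sampling (ms).
#' @param e_rev reversal potential (mV).
#' @return the simulation results, invisibly.
#' @export
plot_protocol_and_currents <- function(protocol, models = list(beattie_model(),
                                                               wang_model()),
                                       file = NULL, dt_out = 1, e_rev = -88) {
  sims <- lapply(models, simulate_current, protocol = protocol,
                 dt_out = dt_out, e_rev = e_rev)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  t <- sims[[1]]$times
  graphics::plot(t, sims[[1]]$voltages, type = "l", xlab = "time (ms)",
                 ylab = "voltage (mV)", main = protocol$name)
  ylim <- range(unlist(lapply(sims, `[[`, "current")))
  graphics::plot(t, sims[[1]]$current, type = "l", ylim = ylim,
                 xlab = "time (ms)", ylab = "current (0.1 nA)")
  if (length(sims) > 1)
    for (i in 2:length(sims))
      graphics::lines(t, sims[[i]]$current, col = i)
  graphics::legend("topleft", legend = vapply(sims, `[[`, "", "model"),
                   col = seq_along(sims), lty = 1, bty = "n")
  invisible(sims)
}
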