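#' Square-wave voltage protocol specification
#'
#' A sum of `N` signed square waves around an offset:
#' `V(t) = b + sum_i a_i * sign(sin(omega_i * t + phi_i))`, where `sign(0)=0`.
#' Amplitudes `a_i` are in mV, angular frequencies `omega_i` in rad/ms
#' (the published frequencies are quoted in ms; they are interpreted here as
#' angular frequencies in rad/ms), phases `phi_i` in rad, offset `b` in mV.
#'
#' @param amplitudes positive amplitudes `a_i` (mV).
#' @param omegas angular frequencies (rad/ms), positive.
#' @param phis phases (rad); recycled to the component count.
#' @param b offset voltage (mV).
#' @return an object of class `square_wave_spec`.
#' @export
square_wave_spec <- function(amplitudes, omegas, phis = 0, b = -30) {
  n <- length(amplitudes)
  if (n < 1) stop("need at least one square-wave component")
  if (length(omegas) != n) stop("'omegas' must match 'amplitudes' in length")
  phis <- rep_len(phis, n)
  if (any(amplitudes <= 0)) stop("amplitudes must be positive")
  if (any(omegas <= 0)) stop("angular frequencies must be positive")
  structure(list(a = as.numeric(amplitudes), omega = as.numeric(omegas),
                 phi = as.numeric(phis), b = as.numeric(b)),
            class = "square_wave_spec")
}

#' @export
print.square_wave_spec <- function(x, ...) {
  cat("Square-wave spec:", length(x$a), "component(s), offset", x$b, "mV\n")
  print(data.frame(a_mV = x$a, omega_rad_per_ms = x$omega, phi_rad = x$phi))
  invisible(x)
}

#' The published three-component square-wave conversion
#'
#' Direct square-wave conversion of a sinusoidal information-rich protocol:
#' amplitudes 54, 26, 10 mV, angular frequencies 0.007, 0.037, 0.19 rad/ms,
#' zero phases, offset -30 mV.
#' @return a [square_wave_spec()].
#' @export
squarewave_paper_spec <- function() {
  square_wave_spec(amplitudes = c(54, 26, 10),
                   omegas = c(0.007, 0.037, 0.19),
                   phis = c(0, 0, 0), b = -30)
}

#' Evaluate a square-wave spec at given times
#'
#' @param s a [square_wave_spec()].
#' @param t times in ms (vector).
#' @return voltages in mV, `b + sum_i a_i * sign(sin(omega_i t + phi_i))`
#'   with `sign(0) = 0`.
#' @export
square_wave_voltage <- function(s, t) {
  stopifnot(inherits(s, "square_wave_spec"), is.numeric(t))
  v <- rep(s$b, length(t))
  for (i in seq_along(s$a))
    v <- v + s$a[i] * sign(sin(s$omega[i] * t + s$phi[i]))
  v
}

#' Convert a square-wave spec to a step protocol
#'
#' Hardware consumes step lists, not closed forms.  The breakpoints are the
#' union of the zero-crossing times of all components (`sin(omega_i t +
#' phi_i) = 0`), sorted and de-duplicated within 1e-9 ms; each resulting
#' interval becomes one constant step whose voltage is the closed-form value
#' at the interval midpoint.  The emitted steps therefore reproduce the
#' closed form exactly everywhere except the measure-zero switching instants.
#'
#' @param s a [square_wave_spec()].
#' @param total_duration protocol body duration in ms, > 0.
#' @param max_segments refuse specs producing more than this many steps.
#' @param name protocol label.
#' @return a [clamp_protocol()] of steps.
#' @export
square_wave_to_segments <- function(s, total_duration, max_segments = 1000L,
                                    name = "squarewave") {
  stopifnot(inherits(s, "square_wave_spec"))
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop("'total_duration' must be positive (ms)")
  cross <- unlist(lapply(seq_along(s$a), function(i) {
    # sin(w t + phi) = 0  at  t = (k*pi - phi)/w
    w <- s$omega[i]; phi <- s$phi[i]
    k0 <- ceiling(phi / pi + 1e-15)
    k1 <- floor((w * total_duration + phi) / pi - 1e-15)
    if (k0 > k1) return(numeric(0))
    ((k0:k1) * pi - phi) / w
  }))
  cross <- sort(cross[cross > 1e-12 & cross < total_duration - 1e-12])
  if (length(cross) > 1)
    cross <- cross[c(TRUE, diff(cross) > 1e-9)]
  breaks <- c(0, cross, total_duration)
  n_seg <- length(breaks) - 1L
  if (n_seg > max_segments)
    stop("square-wave conversion needs ", n_seg,
         " segments, exceeding max_segments = ", max_segments)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  segs <- data.frame(kind = "step", duration = diff(breaks),
                     v_start = square_wave_voltage(s, mids),
                     v_end = square_wave_voltage(s, mids),
                     stringsAsFactors = FALSE)
  clamp_protocol(segs, name = name)
}
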