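#' Hodgkin-Huxley gate steady states and time constants
#'
#' The four-state model is equivalent to two independent first-order gates:
#' an activation gate `a` with `da/dt = k1*(1-a) - k2*a` and an inactivation
#' (recovery) gate `r` with `dr/dt = k4*(1-r) - k3*r`; the open probability
#' is the product `a*r`.
#'
#' @param V voltage(s) in mV.
#' @param p Beattie-type [kinetic_parameters()].
#' @return a data frame with columns `a_inf`, `tau_a` (ms), `r_inf`,
#'   `tau_r` (ms).
#' @export
hh_gate_inf <- function(V, p = beattie_parameters()) {
  k <- beattie_rates(V, p)
  if (is.null(dim(k))) k <- matrix(k, nrow = 1, dimnames = list(NULL, names(k)))
  data.frame(a_inf = k[, "k1"] / (k[, "k1"] + k[, "k2"]),
             tau_a = 1 / (k[, "k1"] + k[, "k2"]),
             r_inf = k[, "k4"] / (k[, "k3"] + k[, "k4"]),
             tau_r = 1 / (k[, "k3"] + k[, "k4"]))
}

# Global half-open output grid: sample indices k with
# start <= k*dt < start + duration (tolerance guards FP drift).
.grid_times <- function(start, duration, dt) {
  k0 <- ceiling(start / dt - 1e-9)
  k1 <- ceiling((start + duration) / dt - 1e-9) - 1
  if (k0 > k1) return(numeric(0))
  (k0:k1) * dt
}

# Advance HH gates through one protocol segment; return samples + end state.
.hh_segment <- function(seg, p, a0, r0, t_start, dt_out, rtol, atol) {
  tl <- .grid_times(t_start, seg$duration, dt_out) - t_start
  if (seg$kind == "step") {
    gi <- hh_gate_inf(seg$v_start, p)
    rel <- function(x0, xinf, tau, t) xinf + (x0 - xinf) * exp(-t / tau)
    a <- rel(a0, gi$a_inf, gi$tau_a, tl)
    r <- rel(r0, gi$r_inf, gi$tau_r, tl)
    a_end <- rel(a0, gi$a_inf, gi$tau_a, seg$duration)
    r_end <- rel(r0, gi$r_inf, gi$tau_r, seg$duration)
    v <- rep(seg$v_start, length(tl))
  } else {
    slope <- (seg$v_end - seg$v_start) / seg$duration
    deriv <- function(t, y, parms) {
      k <- beattie_rates(seg$v_start + slope * t, p)
      list(c(k[["k1"]] * (1 - y[1]) - k[["k2"]] * y[1],
             k[["k4"]] * (1 - y[2]) - k[["k3"]] * y[2]))
    }
    tt <- sort(unique(c(0, tl, seg$duration)))
    sol <- deSolve::lsoda(c(a0, r0), tt, deriv, rtol = rtol, atol = atol)
    ai <- match(tl, tt)
    a <- sol[ai, 2]; r <- sol[ai, 3]
    a_end <- sol[nrow(sol), 2]; r_end <- sol[nrow(sol), 3]
    v <- seg$v_start + slope * tl
  }
  list(t = tl + t_start, v = v, a = a, r = r, a_end = a_end, r_end = r_end)
}

#' Hodgkin-Huxley gate trajectory under a protocol
#'
#' Integrates the two-gate formulation of the four-state model under an
#' arbitrary step/ramp protocol.  Step segments are advanced by the exact
#' exponential relaxation towards `(a_inf, r_inf)`; ramp segments by adaptive
#' integration.  Output is on the uniform half-open grid
#' `t = 0, dt_out, 2*dt_out, ... < duration`.
#'
#' @param protocol a [clamp_protocol()].
#' @param p Beattie-type [kinetic_parameters()].
#' @param initial either `"steady"` (gates at their steady state for
#'   `holding` mV) or a numeric `c(a, r)` in `[0,1]^2`.
#' @param holding holding potential used for `initial = "steady"` (mV).
#' @param dt_out output sampling interval (ms).
#' @param rtol,atol ramp-integration tolerances.
#' @return a data frame with columns `time`, `v`, `a`, `r`, `open`
#'   (`open = a*r`), plus attributes `a_end`, `r_end` (state at protocol
#'   end).
#' @export
hh_trajectory <- function(protocol, p = beattie_parameters(),
                          initial = "steady", holding = -80, dt_out = 1,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  if (identical(initial, "steady")) {
    gi <- hh_gate_inf(holding, p)
    a0 <- gi$a_inf; r0 <- gi$r_inf
  } else {
    if (!is.numeric(initial) || length(initial) != 2 ||
        any(initial < 0) || any(initial > 1))
      stop("'initial' must be c(a, r) within [0, 1]")
    a0 <- initial[1]; r0 <- initial[2]
  }
  segs <- protocol$segments
  starts <- cumsum(c(0, segs$duration))
  out <- vector("list", nrow(segs))
  for (j in seq_len(nrow(segs))) {
    res <- .hh_segment(segs[j, ], p, a0, r0, starts[j], dt_out, rtol, atol)
    a0 <- res$a_end; r0 <- res$r_end
    out[[j]] <- res
  }
  df <- data.frame(time = unlist(lapply(out, `[[`, "t")),
                   v = unlist(lapply(out, `[[`, "v")),
                   a = unlist(lapply(out, `[[`, "a")),
                   r = unlist(lapply(out, `[[`, "r")))
  df$open <- df$a * df$r
  attr(df, "a_end") <- a0
  attr(df, "r_end") <- r0
  df
}

#' Open-probability trajectory of the two-gate formulation
#'
#' Convenience wrapper around [hh_trajectory()] returning the product
#' `a*r`, the open probability of the equivalent four-state Markov model.
#'
#' @inheritParams hh_trajectory
#' @return a data frame with columns `time`, `v`, `a`, `r`, `open`.
#' @export
hh_open_probability <- function(p = beattie_parameters(), protocol,
                                initial = "steady", holding = -80,
                                dt_out = 1) {
  hh_trajectory(protocol, p, initial = initial, holding = holding,
                dt_out = dt_out)
}
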