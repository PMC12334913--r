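# Matrix exponential of a small dense generator (delegates to Matrix).
.expm <- function(A) as.matrix(Matrix::expm(A))

# Advance x' = A x through a constant-voltage segment.  local_times are
# sample offsets within [0, duration); returns samples and the end state.
.propagate_step <- function(A, x0, duration, local_times) {
  n <- length(x0)
  m <- length(local_times)
  states <- matrix(NA_real_, m, n)
  x <- as.numeric(x0)
  t_end <- if (m) local_times[m] else 0
  dts <- c(diff(c(0, local_times)), duration - t_end)
  ud <- unique(dts[dts > 1e-12])
  Es <- lapply(ud, function(d) .expm(A * d))
  idx <- match(dts, ud)  # NA where dt ~ 0
  for (i in seq_len(m)) {
    if (!is.na(idx[i])) x <- Es[[idx[i]]] %*% x
    states[i, ] <- x
  }
  if (!is.na(idx[m + 1L])) x <- Es[[idx[m + 1L]]] %*% x
  list(states = states, end = as.numeric(x))
}

# Advance through one segment with the requested solver.
.markov_segment <- function(model, seg, x0, t_start, dt_out, method,
                            rtol, atol, seg_index) {
  tl <- .grid_times(t_start, seg$duration, dt_out) - t_start
  n <- length(x0)
  if (seg$kind == "step" && method == "propagator") {
    A <- transition_matrix(model, seg$v_start)
    res <- .propagate_step(A, x0, seg$duration, tl)
    states <- res$states; x_end <- res$end
  } else {
    slope <- (seg$v_end - seg$v_start) / seg$duration
    vt <- function(t) seg$v_start + slope * t
    tt <- sort(unique(c(0, tl, seg$duration)))
    if (method == "reduced") {
      deriv <- function(t, y, parms) {
        A <- model$matrix_fn(vt(t), model$params)
        x <- c(y, 1 - sum(y))
        list((A %*% x)[seq_len(n - 1)])
      }
      sol <- tryCatch(
        deSolve::lsoda(x0[seq_len(n - 1)], tt, deriv, rtol = rtol, atol = atol),
        error = function(e) stop("ODE solver failed in segment ", seg_index,
                                 ": ", conditionMessage(e)))
      full <- cbind(sol[, -1, drop = FALSE],
                    1 - rowSums(sol[, -1, drop = FALSE]))
    } else {
      deriv <- function(t, y, parms) {
        A <- model$matrix_fn(vt(t), model$params)
        list(as.numeric(A %*% y))
      }
      sol <- tryCatch(
        deSolve::lsoda(x0, tt, deriv, rtol = rtol, atol = atol),
        error = function(e) stop("ODE solver failed in segment ", seg_index,
                                 ": ", conditionMessage(e)))
      full <- sol[, -1, drop = FALSE]
    }
    ai <- match(tl, tt)
    states <- full[ai, , drop = FALSE]
    x_end <- as.numeric(full[nrow(full), ])
  }
  v <- if (seg$kind == "step") rep(seg$v_start, length(tl))
       else seg$v_start + (seg$v_end - seg$v_start) * tl / seg$duration
  list(t = tl + t_start, v = v, states = states, end = x_end)
}

#' Simulate a gating model under a voltage-clamp protocol
#'
#' Solves `dx/dt = A(V(t)) x` and returns state occupancies, open
#' probability and current `I = g * P(open) * (V - e_rev)` on a uniform
#' half-open output grid.  Constant-voltage segments are advanced by the
#' exact matrix-exponential propagator (`method = "propagator"`, the
#' default); ramps always use adaptive integration.  `method = "adaptive"`
#' integrates everything adaptively; `method = "reduced"` eliminates the
#' last state ("one minus the sum of the rest") and integrates the reduced
#' system, as a numerical-stability cross-check.
#'
#' @param model a [gating_model()].
#' @param protocol a [clamp_protocol()].
#' @param x0 initial occupancy vector, or `"steady"` for the steady state at
#'   `holding` mV (the holding potential both common clamp sections end at).
#' @param holding holding potential for `x0 = "steady"` (mV).
#' @param dt_out output sampling interval in ms (default 1 ms).
#' @param method `"propagator"`, `"adaptive"` or `"reduced"`.
#' @param e_rev reversal potential in mV (default -88.0, a room-temperature
#'   K+ Nernst-style default).
#' @param rtol,atol adaptive-integration tolerances.
#' @return an object of class `clamp_simulation`: list with `times`,
#'   `voltages`, `states` (matrix, one row per time), `open_prob`,
#'   `current` (units 0.1 uS * mV = 0.1 nA), and the call ingredients.
#' @export
simulate_current <- function(model, protocol, x0 = "steady", holding = -80,
                             dt_out = 1, method = c("propagator", "adaptive",
                                                    "reduced"),
                             e_rev = -88, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "gating_model"), inherits(protocol, "clamp_protocol"))
  method <- match.arg(method)
  n <- length(model$state_names)
  if (identical(x0, "steady")) {
    x0 <- steady_state(model, holding)
  } else {
    if (!is.numeric(x0) || length(x0) != n)
      stop("'x0' must be a probability vector of length ", n)
    if (any(x0 < 0) || abs(sum(x0) - 1) > 1e-8)
      stop("'x0' must be non-negative and sum to 1")
  }
  segs <- protocol$segments
  starts <- cumsum(c(0, segs$duration))
  x <- as.numeric(x0)
  parts <- vector("list", nrow(segs))
  for (j in seq_len(nrow(segs))) {
    res <- .markov_segment(model, segs[j, ], x, starts[j], dt_out, method,
                           rtol, atol, j)
    x <- res$end
    parts[[j]] <- res
  }
  times <- unlist(lapply(parts, `[[`, "t"))
  voltages <- unlist(lapply(parts, `[[`, "v"))
  states <- do.call(rbind, lapply(parts, `[[`, "states"))
  colnames(states) <- model$state_names
  open_prob <- states[, model$open_state]
  current <- model$params$g * open_prob * (voltages - e_rev)
  structure(list(times = times, voltages = voltages, states = states,
                 open_prob = open_prob, current = current,
                 final_state = x, model = model$name, protocol = protocol$name,
                 dt_out = dt_out, e_rev = e_rev, method = method),
            class = "clamp_simulation")
}

#' @export
print.clamp_simulation <- function(x, ...) {
  cat("Simulation of model '", x$model, "' under protocol '", x$protocol,
      "': ", length(x$times), " samples at ", x$dt_out, " ms (",
      x$method, ")\n", sep = "")
  cat("  current range [", format(min(x$current), digits = 4), ", ",
      format(max(x$current), digits = 4), "] x 0.1 nA\n", sep = "")
  invisible(x)
}

#' Root-mean-square deviation between two traces
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmsd <- function(x, y) {
  if (length(x) != length(y))
    stop("trace length mismatch: ", length(x), " vs ", length(y))
  sqrt(mean((x - y)^2))
}

.with_param <- function(params, name, factor) {
  if (name == "g") {
    params$g <- params$g * factor
  } else {
    if (!name %in% names(params$values)) stop("unknown parameter '", name, "'")
    params$values[[name]] <- params$values[[name]] * factor
  }
  params
}

.model_with_params <- function(model, params) {
  model$params <- params
  model
}

#' Scaled local parameter sensitivities of the current
#'
#' First-order central differences of the current with respect to each
#' kinetic parameter, scaled by the parameter:
#' `S_i(t) = dI/dp_i * p_i ~ (I(p_i*(1+delta)) - I(p_i*(1-delta))) /
#' (2*delta)` with `delta = delta_frac` (default 0.1%).  Each perturbed run
#' re-derives its own steady-state initial condition, as the physical
#' experiment would equilibrate under the perturbed kinetics.
#'
#' @inheritParams simulate_current
#' @param delta_frac relative perturbation (default 0.001).
#' @param include_conductance also differentiate with respect to `g`
#'   (for which the scaled sensitivity is exactly the current itself).
#' @param parameters which kinetic parameters to differentiate (default all).
#' @return an object of class `sensitivity_result`: list with `times`,
#'   `S` (matrix, one column per parameter, same units as the current) and
#'   `parameters`.
#' @export
local_sensitivities <- function(model, protocol, delta_frac = 0.001,
                                include_conductance = FALSE,
                                parameters = names(model$params$values),
                                holding = -80, dt_out = 1,
                                method = "propagator", e_rev = -88) {
  stopifnot(delta_frac > 0)
  if (any(model$params$values[parameters] == 0) ||
      (include_conductance && model$params$g == 0))
    stop("relative perturbation undefined for a parameter equal to 0")
  pnames <- c(parameters, if (include_conductance) "g")
  sims <- lapply(pnames, function(nm) {
    up <- simulate_current(.model_with_params(model, .with_param(model$params, nm, 1 + delta_frac)),
                           protocol, x0 = "steady", holding = holding,
                           dt_out = dt_out, method = method, e_rev = e_rev)
    dn <- simulate_current(.model_with_params(model, .with_param(model$params, nm, 1 - delta_frac)),
                           protocol, x0 = "steady", holding = holding,
                           dt_out = dt_out, method = method, e_rev = e_rev)
    (up$current - dn$current) / (2 * delta_frac)
  })
  S <- do.call(cbind, sims)
  colnames(S) <- pnames
  ref <- simulate_current(model, protocol, x0 = "steady", holding = holding,
                          dt_out = dt_out, method = method, e_rev = e_rev)
  structure(list(times = ref$times, S = S, parameters = pnames,
                 model = model$name, protocol = protocol$name),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Scaled local sensitivities (", x$model, " / ", x$protocol, "): ",
      nrow(x$S), " times x ", ncol(x$S), " parameters\n", sep = "")
  invisible(x)
}
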