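#' Voltage-dependent rate laws of the four-state hERG model
#'
#' The four-state (Beattie-type) model has two voltage-activated rates
#' `k1 = p1*exp(p2*V)`, `k3 = p5*exp(p6*V)` and two voltage-deactivated rates
#' `k2 = p3*exp(-p4*V)`, `k4 = p7*exp(-p8*V)`.  `k1/k2` govern activation and
#' `k3/k4` inactivation.
#'
#' @param V membrane voltage in mV; may be a vector.
#' @param p a [kinetic_parameters()] object with values `p1..p8`.
#' @return for scalar `V` a named numeric vector `k1..k4` (ms^-1); for vector
#'   `V` a matrix with one row per voltage and columns `k1..k4`.
#' @export
beattie_rates <- function(V, p = beattie_parameters()) {
  .check_voltage(V)
  v <- p$values
  out <- cbind(k1 = v[["p1"]] * exp( v[["p2"]] * V),
               k2 = v[["p3"]] * exp(-v[["p4"]] * V),
               k3 = v[["p5"]] * exp( v[["p6"]] * V),
               k4 = v[["p7"]] * exp(-v[["p8"]] * V))
  if (length(V) == 1L) out[1L, ] else out
}

#' Voltage-dependent rate laws of the five-state hERG model
#'
#' The five-state (Wang-type) model chain C1-C2-C3-O-I uses six
#' voltage-dependent rates, `a1 = q1*exp(q2*V)`, `aa0 = q3*exp(q4*V)`,
#' `aa1 = q5*exp(q6*V)`, `ba1 = q7*exp(-q8*V)`, `b1 = q9*exp(-q10*V)`,
#' `ba0 = q11*exp(-q12*V)`, plus the voltage-independent C2<->C3 rates
#' `kf` (forward) and `kb` (backward).
#'
#' @inheritParams beattie_rates
#' @param q a [kinetic_parameters()] object with values `kb`, `kf`, `q1..q12`.
#' @return for scalar `V` a named numeric vector with elements `a1`, `aa0`,
#'   `aa1`, `ba1`, `b1`, `ba0`, `kf`, `kb` (ms^-1); for vector `V` a matrix.
#' @export
wang_rates <- function(V, q = wang_parameters()) {
  .check_voltage(V)
  v <- q$values
  one <- rep(1, length(V))
  out <- cbind(a1  = v[["q1"]]  * exp( v[["q2"]]  * V),
               aa0 = v[["q3"]]  * exp( v[["q4"]]  * V),
               aa1 = v[["q5"]]  * exp( v[["q6"]]  * V),
               ba1 = v[["q7"]]  * exp(-v[["q8"]]  * V),
               b1  = v[["q9"]]  * exp(-v[["q10"]] * V),
               ba0 = v[["q11"]] * exp(-v[["q12"]] * V),
               kf  = v[["kf"]] * one,
               kb  = v[["kb"]] * one)
  if (length(V) == 1L) out[1L, ] else out
}

.check_voltage <- function(V) {
  if (!is.numeric(V) || length(V) < 1 || any(!is.finite(V)))
    stop("voltage 'V' must be finite numeric (mV)")
  invisible(V)
}

#' Construct a continuous-time Markov gating model
#'
#' A gating model is a linear ODE system `dx/dt = A(V) x` over state
#' occupancies `x`, with a designated open state, a rate law mapping voltage
#' to transition rates, and a transition-matrix builder.  Columns of `A` sum
#' to zero (probability conservation) and off-diagonal entries are
#' non-negative.
#'
#' @param name model label.
#' @param state_names ordered state labels.
#' @param open_state index (or name) of the conducting state.
#' @param rate_fn `function(V, params)` returning named rates.
#' @param matrix_fn `function(V, params)` returning the square transition
#'   matrix `A(V)` in ms^-1.
#' @param params a [kinetic_parameters()] object.
#' @return an object of class `gating_model`.
#' @export
gating_model <- function(name, state_names, open_state, rate_fn, matrix_fn,
                         params) {
  stopifnot(is.character(state_names), length(state_names) >= 2,
            is.function(rate_fn), is.function(matrix_fn),
            inherits(params, "kinetic_parameters"))
  if (is.character(open_state)) open_state <- match(open_state, state_names)
  open_state <- as.integer(open_state)
  if (is.na(open_state) || open_state < 1 || open_state > length(state_names))
    stop("'open_state' must identify one of the model states")
  structure(list(name = name, state_names = state_names,
                 open_state = open_state, rate_fn = rate_fn,
                 matrix_fn = matrix_fn, params = params),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Gating model '", x$name, "': states [",
      paste(x$state_names, collapse = ", "), "], open state ",
      x$state_names[x$open_state], "\n", sep = "")
  cat("  g =", x$params$g, "(0.1 uS);",
      length(x$params$values), "kinetic parameters\n")
  invisible(x)
}

#' The four-state (Beattie-type) hERG gating model
#'
#' Symmetric four-state Markov model over `[C, I, IC, O]`, equivalent to a
#' two-gate Hodgkin-Huxley model (activation gate `a`, inactivation gate `r`,
#' open probability `a*r`).
#'
#' @param params a [kinetic_parameters()] object (default: published values).
#' @return a [gating_model()] object.
#' @export
beattie_model <- function(params = beattie_parameters()) {
  gating_model(
    name = "beattie",
    state_names = c("C", "I", "IC", "O"),
    open_state = "O",
    rate_fn = beattie_rates,
    matrix_fn = function(V, p) {
      k <- beattie_rates(V, p)
      matrix(c(-k[["k1"]] - k[["k3"]], 0,                    k[["k4"]],             k[["k2"]],
               0,                     -k[["k2"]] - k[["k4"]], k[["k1"]],             k[["k3"]],
               k[["k3"]],              k[["k2"]],            -k[["k1"]] - k[["k4"]], 0,
               k[["k1"]],              k[["k4"]],             0,                    -k[["k2"]] - k[["k3"]]),
             nrow = 4, byrow = TRUE,
             dimnames = list(c("C", "I", "IC", "O"), c("C", "I", "IC", "O")))
    },
    params = params)
}

#' The five-state (Wang-type) hERG gating model
#'
#' Linear-chain five-state Markov model over `[C1, C2, C3, O, I]` with three
#' closed states, an open state, and an inactivated state connected
#' sequentially.
#'
#' @param params a [kinetic_parameters()] object (default: published values).
#' @return a [gating_model()] object.
#' @export
wang_model <- function(params = wang_parameters()) {
  gating_model(
    name = "wang",
    state_names = c("C1", "C2", "C3", "O", "I"),
    open_state = "O",
    rate_fn = wang_rates,
    matrix_fn = function(V, q) {
      r <- wang_rates(V, q)
      s <- c("C1", "C2", "C3", "O", "I")
      matrix(c(-r[["aa0"]], r[["ba0"]],                0,                          0,                        0,
               r[["aa0"]], -r[["ba0"]] - r[["kf"]],    r[["kb"]],                  0,                        0,
               0,           r[["kf"]],                -r[["kb"]] - r[["aa1"]],     r[["ba1"]],               0,
               0,           0,                         r[["aa1"]],                -r[["ba1"]] - r[["a1"]],   r[["b1"]],
               0,           0,                         0,                          r[["a1"]],               -r[["b1"]]),
             nrow = 5, byrow = TRUE, dimnames = list(s, s))
    },
    params = params)
}

#' Transition matrix of a gating model at a voltage
#'
#' @param model a [gating_model()].
#' @param V voltage in mV (scalar).
#' @return the square matrix `A(V)` (ms^-1); columns sum to zero.
#' @export
transition_matrix <- function(model, V) {
  stopifnot(inherits(model, "gating_model"), length(V) == 1L)
  .check_voltage(V)
  model$matrix_fn(V, model$params)
}

#' Steady-state occupancy of a gating model at a fixed voltage
#'
#' Solves `A(V) x = 0` subject to `sum(x) = 1`.  Fails explicitly when the
#' transition matrix is degenerate (null space not one-dimensional) rather
#' than returning NaN.
#'
#' @inheritParams transition_matrix
#' @return a named probability vector (non-negative, sums to 1).
#' @export
steady_state <- function(model, V) {
  A <- transition_matrix(model, V)
  n <- nrow(A)
  M <- rbind(A, rep(1, n))
  x <- tryCatch(qr.solve(M, c(rep(0, n), 1)), error = function(e)
    stop("degenerate transition matrix at V = ", V, " mV: ", conditionMessage(e)))
  if (any(!is.finite(x)) || max(abs(A %*% x)) > 1e-10 || any(x < -1e-12))
    stop("no valid steady state at V = ", V,
         " mV (reducible or ill-conditioned transition matrix)")
  x <- pmax(x, 0)
  stats::setNames(x / sum(x), model$state_names)
}
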