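#' Phase-voltage space grid
#'
#' Box discretisation of the `(a, r, V)` phase-voltage space of the
#' four-state model: activation gate in `[0,1]`, inactivation gate in
#' `[0,1]`, voltage in `[-120, 60]` mV, each subdivided into 6 compartments
#' by default, giving `6^3 = 216` boxes.  Bins are half-open with the upper
#' boundary of the last bin closed.
#'
#' @param bounds list of three `c(lo, hi)` pairs for `a`, `r`, `V`.
#' @param subdivisions integer vector of three bin counts.
#' @return an object of class `phase_grid` with element `n_boxes`.
#' @export
phase_grid <- function(bounds = list(c(0, 1), c(0, 1), c(-120, 60)),
                       subdivisions = c(6L, 6L, 6L)) {
  stopifnot(length(bounds) == 3, length(subdivisions) == 3,
            all(subdivisions >= 1))
  for (b in bounds) if (b[1] >= b[2]) stop("grid bounds must be ordered")
  structure(list(bounds = bounds, subdivisions = as.integer(subdivisions),
                 n_boxes = as.integer(prod(subdivisions))),
            class = "phase_grid")
}

# Linear box indices (1-based) of trajectory points; clamps out-of-range
# samples into the edge bins with a warning.
.phase_box_index <- function(a, r, v, grid) {
  dims <- grid$subdivisions
  idx1 <- function(x, bnd, nb) {
    if (any(x < bnd[1] - 1e-9) || any(x > bnd[2] + 1e-9))
      warning("trajectory samples outside phase-grid bounds were clamped ",
              "into edge bins")
    i <- floor((x - bnd[1]) / (bnd[2] - bnd[1]) * nb)
    pmin(pmax(i, 0L), nb - 1L)  # closed top edge + clamping
  }
  ia <- idx1(a, grid$bounds[[1]], dims[1])
  ir <- idx1(r, grid$bounds[[2]], dims[2])
  iv <- idx1(v, grid$bounds[[3]], dims[3])
  as.integer(ia + dims[1] * ir + dims[1] * dims[2] * iv + 1L)
}

#' Phase-voltage space coverage of a trajectory
#'
#' Bins `(a, r, V)` samples into the phase grid and counts how many *new*
#' boxes (not in `already_visited`) the trajectory enters.
#'
#' @param trajectory a data frame or matrix with columns `a`, `r`, `v`
#'   (1 ms samples of the gate trajectory and command voltage).
#' @param grid a [phase_grid()].
#' @param already_visited integer vector of previously visited box indices.
#' @return list with `new_boxes` (count), `visited` (updated sorted index
#'   set) and `boxes` (indices touched by this trajectory).
#' @export
phase_coverage <- function(trajectory, grid = phase_grid(),
                           already_visited = integer(0)) {
  trajectory <- as.data.frame(trajectory)
  stopifnot(all(c("a", "r", "v") %in% names(trajectory)))
  boxes <- unique(.phase_box_index(trajectory$a, trajectory$r, trajectory$v,
                                   grid))
  new_boxes <- sum(!(boxes %in% already_visited))
  list(new_boxes = new_boxes,
       visited = sort(unique(c(already_visited, boxes))),
       boxes = sort(boxes))
}

#' Sample kinetic parameter vectors from a prior range
#'
#' Draws `M` parameter vectors from the box `[lower, upper]`.  The default
#' draw is log-uniform: the published ranges span up to five orders of
#' magnitude, so uniform draws would concentrate in the top decade.
#'
#' @param ranges a [parameter_ranges()].
#' @param M number of samples (>= 2 for pairwise objectives).
#' @param scale `"log"` (log-uniform, default) or `"linear"`.
#' @param seed RNG seed.
#' @return an object of class `parameter_sample_set`: list with `samples`
#'   (M x d matrix, columns named) plus the draw metadata.
#' @export
sample_parameters <- function(ranges, M, scale = c("log", "linear"),
                              seed = 1L) {
  stopifnot(inherits(ranges, "parameter_ranges"), M >= 1)
  scale <- match.arg(scale)
  d <- length(ranges$lower)
  set.seed(seed)
  u <- matrix(stats::runif(M * d), M, d)
  samples <- if (scale == "log") {
    exp(sweep(sweep(u, 2, log(ranges$upper) - log(ranges$lower), "*"),
              2, log(ranges$lower), "+"))
  } else {
    sweep(sweep(u, 2, ranges$upper - ranges$lower, "*"), 2, ranges$lower, "+")
  }
  colnames(samples) <- names(ranges$lower)
  structure(list(samples = samples, scale = scale, seed = seed,
                 ranges = ranges),
            class = "parameter_sample_set")
}

# ---- unit helpers ----------------------------------------------------------

#' A three-step design unit
#'
#' @param v voltages of the three steps (mV).
#' @param dt durations of the three steps (ms).
#' @param free_mask logical length 6 (`V1..V3, dt1..dt3`): which scalars the
#'   optimiser may move (others are frozen, e.g. at random draws in
#'   Gibbs-style designs).
#' @return an object of class `design_unit`.
#' @export
design_unit <- function(v, dt, free_mask = rep(TRUE, 6)) {
  stopifnot(length(v) == 3, length(dt) == 3, length(free_mask) == 6)
  if (any(dt <= 0)) stop("step durations must be positive")
  structure(list(v = as.numeric(v), dt = as.numeric(dt),
                 free_mask = as.logical(free_mask)),
            class = "design_unit")
}

#' @export
print.design_unit <- function(x, ...) {
  cat("3-step unit: V =", paste(x$v, collapse = ", "), "mV; dt =",
      paste(x$dt, collapse = ", "), "ms\n")
  invisible(x)
}

.unit_to_protocol <- function(unit) {
  clamp_protocol(data.frame(kind = "step", duration = unit$dt,
                            v_start = unit$v, v_end = unit$v),
                 name = "unit")
}

# context (protocol) + unit appended; returns protocol and the index range of
# output samples (at dt_out) that fall in step `which_steps` of the unit.
.unit_window <- function(context, unit, dt_out, which_steps = 1:3) {
  proto <- concat_protocols(context, .unit_to_protocol(unit), name = "ctx+unit")
  off <- protocol_duration(context)
  starts <- off + cumsum(c(0, unit$dt))
  lo <- starts[min(which_steps)]
  hi <- starts[max(which_steps) + 1]
  times <- .grid_times(0, protocol_duration(proto), dt_out)
  sel <- which(times >= lo - 1e-9 & times < hi - 1e-9)
  list(protocol = proto, window = sel, times = times)
}

# ---- objectives ------------------------------------------------------------

#' Local-sensitivity design objective for one parameter
#'
#' Normalised scaled-sensitivity mass of parameter `i` over the *third* step
#' of a three-step unit appended to `context`:
#' `S_i = int |dI/dp_i p_i| dt / sum_k int |dI/dp_k p_k| dt`, integrated by
#' rectangle rule on the output grid over the last step only.  The first two
#' steps are free to set up the state.  Values lie in `[0, 1]`; when no
#' parameter carries any sensitivity over the window the value is 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param i parameter index (into the model's kinetic parameter vector).
#' @param unit a [design_unit()].
#' @param context a [clamp_protocol()] preceding the unit (typically the
#'   common head plus previously fixed units).
#' @param model a [gating_model()].
#' @param delta_frac central-difference relative step (default 0.001).
#' @param dt_out output sampling (ms).
#' @return scalar in `[0, 1]`.
#' @export
local_sensitivity_objective <- function(i, unit, context, model,
                                        delta_frac = 0.001, dt_out = 1) {
  pn <- names(model$params$values)
  if (!(is.numeric(i) && i >= 1 && i <= length(pn)))
    stop("invalid parameter index ", i)
  w <- .unit_window(context, unit, dt_out, which_steps = 3)
  sens <- local_sensitivities(model, w$protocol, delta_frac = delta_frac,
                              dt_out = dt_out)
  mass <- colSums(abs(sens$S[w$window, , drop = FALSE])) * dt_out
  denom <- sum(mass)
  if (denom < 1e-300) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  unname(mass[i] / denom)
}

#' First-order Sobol sensitivity estimator
#'
#' Saltelli-scheme estimator of first-order Sobol indices for a vector- (or
#' scalar-) valued function of `d` independent uniform inputs on
#' `[lower, upper]`.  Uses Latin-hypercube base samples `A`, `B` and the
#' radial matrices `AB_i`, the Jansen estimator for `V_i`, and is
#' deterministic given `seed`.
#'
#' @param fn function taking an `n x d` matrix of parameter rows and
#'   returning an `n x T` matrix of outputs (or a length-`n` vector).
#' @param lower,upper parameter bounds (length `d`).
#' @param n_base base sample size `n`.
#' @param seed RNG seed.
#' @param log_scale sample log-uniformly within the bounds.
#' @return a `d x T` matrix of first-order indices, clipped to `[0, 1]`;
#'   columns where `Var(Y)` underflows are set to 0.
#' @export
sobol_first_order <- function(fn, lower, upper, n_base = 1024L, seed = 1L,
                              log_scale = FALSE) {
  d <- length(lower)
  stopifnot(length(upper) == d, n_base >= 2)
  mats <- .sobol_matrices(lower, upper, n_base, seed, log_scale)
  as_mat <- function(y) if (is.matrix(y)) y else matrix(y, ncol = 1)
  fA <- as_mat(fn(mats$A)); fB <- as_mat(fn(mats$B))
  S <- matrix(0, d, ncol(fA))
  for (i in seq_len(d)) {
    ABi <- mats$A
    ABi[, i] <- mats$B[, i]
    S[i, ] <- .jansen_first_order(fA, fB, as_mat(fn(ABi)))
  }
  rownames(S) <- names(lower)
  S
}

# Latin-hypercube Saltelli base matrices A, B on [lower, upper].
.sobol_matrices <- function(lower, upper, n_base, seed, log_scale) {
  d <- length(lower)
  set.seed(seed)
  tr <- function(u) {
    if (log_scale)
      exp(sweep(sweep(u, 2, log(upper) - log(lower), "*"), 2, log(lower), "+"))
    else sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  }
  A <- tr(lhs::randomLHS(n_base, d))
  B <- tr(lhs::randomLHS(n_base, d))
  colnames(A) <- colnames(B) <- names(lower)
  list(A = A, B = B)
}

# Per-output-time first-order index of one input, Jansen estimator:
# V_i = Var(Y) - mean((f(B) - f(AB_i))^2)/2, clipped into [0, 1].
.jansen_first_order <- function(fA, fB, fABi) {
  vY <- apply(rbind(fA, fB), 2, stats::var)
  Vi <- vY - colMeans((fB - fABi)^2) / 2
  ifelse(vY > 1e-300, pmin(pmax(Vi / vY, 0), 1), 0)
}

#' First-order Sobol design objective for one parameter
#'
#' First-order Sobol index of parameter `i` for the current over the third
#' step of the unit, `S_i = Var_{p_i}(E_{p_!i}(I | p_i)) / Var(I)`, computed
#' per output time by the Saltelli-type estimator of [sobol_first_order()]
#' with parameters drawn from `ranges`, and aggregated by time-averaging
#' over the window.
#'
#' @inheritParams local_sensitivity_objective
#' @param ranges a [parameter_ranges()] prior box (default: the published
#'   fit-derived ranges for the model family).
#' @param n_base Saltelli base sample size.
#' @param seed RNG seed (estimator is deterministic given the seed).
#' @param log_scale draw parameters log-uniformly.
#' @return scalar in `[0, 1]`; 0 with attribute `degenerate = TRUE` when the
#'   output variance vanishes over the whole window.
#' @export
sobol_first_order_objective <- function(i, unit, context, model,
                                        ranges = NULL, n_base = 128L,
                                        seed = 1L, dt_out = 1,
                                        log_scale = TRUE) {
  pn <- names(model$params$values)
  if (!(is.numeric(i) && i >= 1 && i <= length(pn)))
    stop("invalid parameter index ", i)
  if (is.null(ranges))
    ranges <- if (model$name == "wang") wang_ranges() else beattie_ranges()
  w <- .unit_window(context, unit, dt_out, which_steps = 3)
  fn <- function(P) {
    t(apply(P, 1, function(row) {
      pp <- model$params
      pp$values[colnames(P)] <- row
      sim <- simulate_current(.model_with_params(model, pp), w$protocol,
                              dt_out = dt_out)
      sim$current[w$window]
    }))
  }
  S <- sobol_first_order(fn, ranges$lower, ranges$upper, n_base = n_base,
                         seed = seed, log_scale = log_scale)
  if (all(S == 0)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mean(S[i, ])
}

#' Pairwise-RMSD spread of a set of traces
#'
#' The brute-force sampling score
#' `S = (2/M^2) * sum_{j<k} RMSD(I_j, I_k)`: the (prefactored) sum of
#' root-mean-square deviations between the outputs of all sampled parameter
#' pairs.
#'
#' @param traces an `M x T` matrix, one model-output trace per row.
#' @return scalar >= 0; 0 iff all traces are identical.
#' @export
pairwise_rmsd_spread <- function(traces) {
  stopifnot(is.matrix(traces))
  M <- nrow(traces)
  if (M < 2) stop("need at least M = 2 traces")
  tot <- 0
  for (j in seq_len(M - 1))
    for (k in (j + 1):M)
      tot <- tot + rmsd(traces[j, ], traces[k, ])
  2 * tot / M^2
}

#' Sampled-parameter output-spread design objective
#'
#' Simulates the unit (appended to `context`) for every parameter vector of
#' a sample set and scores the spread of the resulting currents by
#' [pairwise_rmsd_spread()].  Traces are compared over the whole three-step
#' unit window.
#'
#' @inheritParams local_sensitivity_objective
#' @param samples a [sample_parameters()] set (M >= 2).
#' @return scalar >= 0.
#' @export
brute_force_spread_objective <- function(unit, context, model, samples,
                                         dt_out = 1) {
  stopifnot(inherits(samples, "parameter_sample_set"))
  M <- nrow(samples$samples)
  if (M < 2) stop("need at least M = 2 parameter samples")
  w <- .unit_window(context, unit, dt_out, which_steps = 1:3)
  traces <- t(apply(samples$samples, 1, function(row) {
    pp <- model$params
    pp$values[colnames(samples$samples)] <- row
    simulate_current(.model_with_params(model, pp), w$protocol,
                     dt_out = dt_out)$current[w$window]
  }))
  pairwise_rmsd_spread(traces)
}

#' Two-model discrimination design objective
#'
#' RMSD between the currents of two candidate models (each at its own
#' default parameters) over the three-step unit window; a 'local' design
#' with respect to model parameters.
#'
#' @inheritParams local_sensitivity_objective
#' @param model_a,model_b [gating_model()] objects.
#' @return scalar >= 0; symmetric in the model order.
#' @export
model_discrimination_objective <- function(unit, context, model_a, model_b,
                                           dt_out = 1) {
  w <- .unit_window(context, unit, dt_out, which_steps = 1:3)
  ia <- simulate_current(model_a, w$protocol, dt_out = dt_out)$current[w$window]
  ib <- simulate_current(model_b, w$protocol, dt_out = dt_out)$current[w$window]
  rmsd(ia, ib)
}

#' Phase-coverage design objective
#'
#' Number of *new* phase-voltage boxes entered by the four-state model's
#' `(a, r, V)` trajectory during the unit, given the boxes already visited
#' by the preceding protocol.
#'
#' @inheritParams local_sensitivity_objective
#' @param grid a [phase_grid()].
#' @param already_visited integer box indices already visited (if `NULL`,
#'   computed from the context trajectory).
#' @return scalar count >= 0.
#' @export
phase_coverage_objective <- function(unit, context, model, grid = phase_grid(),
                                     already_visited = NULL, dt_out = 1) {
  p <- model$params
  ctx_traj <- hh_trajectory(context, p, dt_out = dt_out)
  if (is.null(already_visited))
    already_visited <- phase_coverage(ctx_traj, grid)$visited
  a0 <- attr(ctx_traj, "a_end"); r0 <- attr(ctx_traj, "r_end")
  off <- protocol_duration(context)
  tr <- .hh_unit_trajectory(unit, p, a0, r0, off, dt_out)
  phase_coverage(data.frame(a = tr$a, r = tr$r, v = tr$v), grid,
                 already_visited)$new_boxes
}

# Fast analytic gate trajectory through the 3 steps of a unit, keeping the
# global output grid (offset `off`).  Same relaxation law as hh_trajectory().
.hh_unit_trajectory <- function(unit, p, a0, r0, off, dt_out) {
  pv <- p$values
  k1 <- pv[["p1"]] * exp( pv[["p2"]] * unit$v)
  k2 <- pv[["p3"]] * exp(-pv[["p4"]] * unit$v)
  k3 <- pv[["p5"]] * exp( pv[["p6"]] * unit$v)
  k4 <- pv[["p7"]] * exp(-pv[["p8"]] * unit$v)
  a_inf <- k1 / (k1 + k2); tau_a <- 1 / (k1 + k2)
  r_inf <- k4 / (k3 + k4); tau_r <- 1 / (k3 + k4)
  t_cur <- off
  out_a <- vector("list", 3); out_r <- out_a; out_v <- out_a
  for (j in 1:3) {
    tl <- .grid_times(t_cur, unit$dt[j], dt_out) - t_cur
    out_a[[j]] <- a_inf[j] + (a0 - a_inf[j]) * exp(-tl / tau_a[j])
    out_r[[j]] <- r_inf[j] + (r0 - r_inf[j]) * exp(-tl / tau_r[j])
    out_v[[j]] <- rep(unit$v[j], length(tl))
    a0 <- a_inf[j] + (a0 - a_inf[j]) * exp(-unit$dt[j] / tau_a[j])
    r0 <- r_inf[j] + (r0 - r_inf[j]) * exp(-unit$dt[j] / tau_r[j])
    t_cur <- t_cur + unit$dt[j]
  }
  list(a = unlist(out_a), r = unlist(out_r), v = unlist(out_v),
       a_end = a0, r_end = r0)
}

# Warning-free box binning used in optimisation loops; identical arithmetic
# to .phase_box_index (designed units cannot leave the grid bounds).
.phase_box_index_fast <- function(a, r, v, grid) {
  dims <- grid$subdivisions
  b1 <- grid$bounds[[1]]; b2 <- grid$bounds[[2]]; b3 <- grid$bounds[[3]]
  ia <- pmin(pmax(floor((a - b1[1]) / (b1[2] - b1[1]) * dims[1]), 0), dims[1] - 1L)
  ir <- pmin(pmax(floor((r - b2[1]) / (b2[2] - b2[1]) * dims[2]), 0), dims[2] - 1L)
  iv <- pmin(pmax(floor((v - b3[1]) / (b3[2] - b3[1]) * dims[3]), 0), dims[3] - 1L)
  as.integer(ia + dims[1] * ir + dims[1] * dims[2] * iv + 1L)
}

#' Registry of design objectives
#'
#' Named access to the protocol-scoring functions used by the iterative
#' designer: `"local_sens"`, `"sobol"`, `"brute_rmsd"`, `"discrim"`,
#' `"spacefill"`.
#'
#' @param name objective name.
#' @return `list_objectives()`: character vector of registered names;
#'   `get_objective()`: the objective function.
#' @export
list_objectives <- function() {
  c("local_sens", "sobol", "brute_rmsd", "discrim", "spacefill")
}

#' @rdname list_objectives
#' @export
get_objective <- function(name) {
  switch(name,
         local_sens = local_sensitivity_objective,
         sobol = sobol_first_order_objective,
         brute_rmsd = brute_force_spread_objective,
         discrim = model_discrimination_objective,
         spacefill = phase_coverage_objective,
         stop("unknown objective '", name, "'; see list_objectives()"))
}
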