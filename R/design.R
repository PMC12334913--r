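#' Configuration for automated protocol design
#'
#' @param objective one of [list_objectives()].
#' @param model a [gating_model()] (the design model).
#' @param model_b second model for discrimination objectives (default: the
#'   five-state model when `model` is the four-state one, and vice versa).
#' @param n_units number of three-step units; default is the number of
#'   kinetic parameters for the per-parameter objectives (`local_sens`,
#'   `sobol`) and 17 otherwise (17 units give a 51-step body, 64 commands
#'   with the common head and tail).
#' @param v_bounds designed step-voltage bounds (mV).
#' @param dt_bounds designed step-duration bounds (ms).
#' @param n_restarts optimiser restarts per unit (default 10).
#' @param seed RNG seed for the whole design (restart starts, frozen Gibbs
#'   draws, parameter samples).
#' @param rounding `c(v, dt)` rounding grid; designed values are rounded to
#'   the nearest 0.1 mV / 0.1 ms before final scoring.
#' @param gibbs_mode `"none"` (all six scalars optimised), `"random_dt"`
#'   (durations frozen at uniform draws, voltages optimised), `"random_v"`
#'   (voltages frozen, durations optimised), or `"alternating"` (odd units
#'   freeze durations, even units freeze voltages).
#' @param gibbs_dt_range,gibbs_v_range uniform draw ranges for frozen
#'   scalars (ms / mV).
#' @param dt_out objective sampling interval (ms, default 1).
#' @param M sample count for the brute-force spread objective.
#' @param sample_scale draw scale for parameter samples.
#' @param n_base Saltelli base sample size for the Sobol objective.
#' @param grid a [phase_grid()] for the space-filling objective.
#' @param e_rev reversal potential (mV).
#' @param cma list of CMA-ES settings: `popsize`, `maxiter`, `sigma0`,
#'   `stop_tol`.
#' @return an object of class `design_config`.
#' @export
design_config <- function(objective = "spacefill", model = beattie_model(),
                          model_b = NULL, n_units = NULL,
                          v_bounds = c(-120, 60), dt_bounds = c(50, 1000),
                          n_restarts = 10L, seed = 1L,
                          rounding = c(v = 0.1, dt = 0.1),
                          gibbs_mode = c("none", "random_dt", "random_v",
                                         "alternating"),
                          gibbs_dt_range = c(50, 1000),
                          gibbs_v_range = c(-120, 60), dt_out = 1,
                          M = 50L, sample_scale = "log", n_base = 64L,
                          grid = phase_grid(), e_rev = -88,
                          cma = list()) {
  objective <- match.arg(objective, list_objectives())
  gibbs_mode <- match.arg(gibbs_mode)
  stopifnot(inherits(model, "gating_model"), n_restarts >= 1,
            v_bounds[1] < v_bounds[2], dt_bounds[1] < dt_bounds[2])
  if (is.null(model_b) && objective == "discrim")
    model_b <- if (model$name == "wang") beattie_model() else wang_model()
  if (is.null(n_units))
    n_units <- if (objective %in% c("local_sens", "sobol"))
      length(model$params$values) else 17L
  if (n_units < 1) stop("'n_units' must be >= 1")
  cma_defaults <- list(popsize = NULL, maxiter = 100L, sigma0 = 1 / 6,
                       stop_tol = 1e-4)
  cma <- utils::modifyList(cma_defaults, cma)
  structure(list(objective = objective, model = model, model_b = model_b,
                 n_units = as.integer(n_units), v_bounds = v_bounds,
                 dt_bounds = dt_bounds, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), rounding = rounding,
                 gibbs_mode = gibbs_mode, gibbs_dt_range = gibbs_dt_range,
                 gibbs_v_range = gibbs_v_range, dt_out = dt_out,
                 M = as.integer(M), sample_scale = sample_scale,
                 n_base = as.integer(n_base), grid = grid, e_rev = e_rev,
                 cma = cma),
            class = "design_config")
}

# Simulate the three steps of a unit from a given Markov state at global time
# offset `off`; returns per-step current vectors and the end state.
.unit_sim <- function(model, unit, x0, off, dt_out, e_rev) {
  t_cur <- off
  x <- x0
  g <- model$params$g
  oc <- model$open_state
  cur <- vector("list", 3)
  for (j in 1:3) {
    A <- transition_matrix(model, unit$v[j])
    tl <- .grid_times(t_cur, unit$dt[j], dt_out) - t_cur
    res <- .propagate_step(A, x, unit$dt[j], tl)
    cur[[j]] <- g * res$states[, oc] * (unit$v[j] - e_rev)
    x <- res$end
    t_cur <- t_cur + unit$dt[j]
  }
  list(currents = cur, end = x)
}

# Per-objective incremental engines.  Each engine provides
#   init()            -> state cached at the end of the common head,
#   value(unit, state, i) -> objective value with the unit appended,
#   accept(unit, state)   -> state advanced through the accepted unit.
# Engine values agree exactly with the public objective functions evaluated
# on head + units[1..i-1] as context (verified by score_design()).
.make_engine <- function(config) {
  head <- common_head()
  model <- config$model
  dt_out <- config$dt_out
  e_rev <- config$e_rev
  switch(config$objective,
    spacefill = {
      p <- model$params
      grid <- config$grid
      # visited is kept as a logical membership vector over the grid boxes;
      # counts agree exactly with phase_coverage() (same binning).
      list(
        init = function() {
          tr <- hh_trajectory(head, p, dt_out = dt_out)
          vis <- logical(grid$n_boxes)
          vis[.phase_box_index_fast(tr$a, tr$r, tr$v, grid)] <- TRUE
          list(visited = vis, a0 = attr(tr, "a_end"),
               r0 = attr(tr, "r_end"), off = protocol_duration(head))
        },
        value = function(unit, state, i) {
          tr <- .hh_unit_trajectory(unit, p, state$a0, state$r0, state$off,
                                    dt_out)
          idx <- .phase_box_index_fast(tr$a, tr$r, tr$v, grid)
          sum(!state$visited[unique(idx)])
        },
        accept = function(unit, state) {
          tr <- .hh_unit_trajectory(unit, p, state$a0, state$r0, state$off,
                                    dt_out)
          vis <- state$visited
          vis[.phase_box_index_fast(tr$a, tr$r, tr$v, grid)] <- TRUE
          list(visited = vis, a0 = tr$a_end, r0 = tr$r_end,
               off = state$off + sum(unit$dt))
        })
    },
    discrim = {
      model_b <- config$model_b
      if (is.null(model_b)) stop("discrimination design needs 'model_b'")
      list(
        init = function() {
          sa <- simulate_current(model, head, dt_out = dt_out, e_rev = e_rev)
          sb <- simulate_current(model_b, head, dt_out = dt_out, e_rev = e_rev)
          list(xa = sa$final_state, xb = sb$final_state,
               off = protocol_duration(head))
        },
        value = function(unit, state, i) {
          ca <- .unit_sim(model, unit, state$xa, state$off, dt_out, e_rev)
          cb <- .unit_sim(model_b, unit, state$xb, state$off, dt_out, e_rev)
          rmsd(unlist(ca$currents), unlist(cb$currents))
        },
        accept = function(unit, state) {
          ca <- .unit_sim(model, unit, state$xa, state$off, dt_out, e_rev)
          cb <- .unit_sim(model_b, unit, state$xb, state$off, dt_out, e_rev)
          list(xa = ca$end, xb = cb$end, off = state$off + sum(unit$dt))
        })
    },
    brute_rmsd = {
      ranges <- if (model$name == "wang") wang_ranges() else beattie_ranges()
      samples <- sample_parameters(ranges, config$M,
                                   scale = config$sample_scale,
                                   seed = config$seed)
      variants <- lapply(seq_len(nrow(samples$samples)), function(m) {
        pp <- model$params
        pp$values[colnames(samples$samples)] <- samples$samples[m, ]
        .model_with_params(model, pp)
      })
      list(
        samples = samples,
        init = function() {
          xs <- lapply(variants, function(mv)
            simulate_current(mv, head, dt_out = dt_out, e_rev = e_rev)$final_state)
          list(xs = xs, off = protocol_duration(head))
        },
        value = function(unit, state, i) {
          traces <- do.call(rbind, lapply(seq_along(variants), function(m)
            unlist(.unit_sim(variants[[m]], unit, state$xs[[m]], state$off,
                             dt_out, e_rev)$currents)))
          pairwise_rmsd_spread(traces)
        },
        accept = function(unit, state) {
          xs <- lapply(seq_along(variants), function(m)
            .unit_sim(variants[[m]], unit, state$xs[[m]], state$off, dt_out,
                      e_rev)$end)
          list(xs = xs, off = state$off + sum(unit$dt))
        })
    },
    local_sens = {
      pn <- names(model$params$values)
      delta <- 0.001
      variants <- list()
      for (nm in pn) {
        variants[[paste0(nm, "+")]] <-
          .model_with_params(model, .with_param(model$params, nm, 1 + delta))
        variants[[paste0(nm, "-")]] <-
          .model_with_params(model, .with_param(model$params, nm, 1 - delta))
      }
      list(
        init = function() {
          xs <- lapply(variants, function(mv)
            simulate_current(mv, head, dt_out = dt_out, e_rev = e_rev)$final_state)
          list(xs = xs, off = protocol_duration(head))
        },
        value = function(unit, state, i) {
          mass <- vapply(seq_along(pn), function(k) {
            up <- .unit_sim(variants[[2 * k - 1]], unit, state$xs[[2 * k - 1]],
                            state$off, dt_out, e_rev)$currents[[3]]
            dn <- .unit_sim(variants[[2 * k]], unit, state$xs[[2 * k]],
                            state$off, dt_out, e_rev)$currents[[3]]
            sum(abs((up - dn) / (2 * delta))) * dt_out
          }, numeric(1))
          denom <- sum(mass)
          if (denom < 1e-300) 0 else mass[i] / denom
        },
        accept = function(unit, state) {
          xs <- lapply(seq_along(variants), function(k)
            .unit_sim(variants[[k]], unit, state$xs[[k]], state$off, dt_out,
                      e_rev)$end)
          list(xs = xs, off = state$off + sum(unit$dt))
        })
    },
    sobol = {
      ranges <- if (model$name == "wang") wang_ranges() else beattie_ranges()
      mats <- .sobol_matrices(ranges$lower, ranges$upper, config$n_base,
                              config$seed, log_scale = TRUE)
      row_model <- function(row) {
        pp <- model$params
        pp$values[names(ranges$lower)] <- row
        .model_with_params(model, pp)
      }
      ctx_states <- function(rows, context) {
        lapply(seq_len(nrow(rows)), function(m)
          simulate_current(row_model(rows[m, ]), context, dt_out = dt_out,
                           e_rev = e_rev)$final_state)
      }
      unit_f <- function(rows, states, unit, off) {
        # third-step currents, one row per parameter sample
        do.call(rbind, lapply(seq_len(nrow(rows)), function(m)
          .unit_sim(row_model(rows[m, ]), unit, states[[m]], off, dt_out,
                    e_rev)$currents[[3]]))
      }
      cache <- new.env(parent = emptyenv())
      cache$i <- -1L
      list(
        init = function() {
          list(context = head, xA = ctx_states(mats$A, head),
               xB = ctx_states(mats$B, head),
               off = protocol_duration(head))
        },
        value = function(unit, state, i) {
          if (!identical(cache$i, i)) {
            ABi <- mats$A
            ABi[, i] <- mats$B[, i]
            cache$ABi <- ABi
            cache$xABi <- ctx_states(ABi, state$context)
            cache$i <- i
          }
          fA <- unit_f(mats$A, state$xA, unit, state$off)
          fB <- unit_f(mats$B, state$xB, unit, state$off)
          fABi <- unit_f(cache$ABi, cache$xABi, unit, state$off)
          mean(.jansen_first_order(fA, fB, fABi))
        },
        accept = function(unit, state) {
          up <- .unit_to_protocol(unit)
          list(context = concat_protocols(state$context, up),
               xA = lapply(seq_len(nrow(mats$A)), function(m)
                 .unit_sim(row_model(mats$A[m, ]), unit, state$xA[[m]],
                           state$off, dt_out, e_rev)$end),
               xB = lapply(seq_len(nrow(mats$B)), function(m)
                 .unit_sim(row_model(mats$B[m, ]), unit, state$xB[[m]],
                           state$off, dt_out, e_rev)$end),
               off = state$off + sum(unit$dt))
        })
    })
}

# Draw frozen scalars and the free mask for unit i under the Gibbs mode.
.gibbs_draw <- function(config, i) {
  mode <- config$gibbs_mode
  freeze_dt <- switch(mode, none = FALSE, random_dt = TRUE, random_v = FALSE,
                      alternating = (i %% 2 == 1))
  freeze_v <- switch(mode, none = FALSE, random_dt = FALSE, random_v = TRUE,
                     alternating = (i %% 2 == 0))
  v <- if (freeze_v)
    stats::runif(3, config$gibbs_v_range[1], config$gibbs_v_range[2])
  else rep(NA_real_, 3)
  dt <- if (freeze_dt)
    stats::runif(3, config$gibbs_dt_range[1], config$gibbs_dt_range[2])
  else rep(NA_real_, 3)
  list(v = v, dt = dt, free_mask = c(!rep(freeze_v, 3), !rep(freeze_dt, 3)))
}

.round_to <- function(x, grid) round(x / grid) * grid

#' Optimise one three-step design unit
#'
#' Maximises an objective over the free scalars of a three-step unit by
#' CMA-ES, restarted `n_restarts` times from uniformly random in-bounds
#' starts.  The returned unit is rounded to the practical 0.1 ms / 0.1 mV
#' grid *before* the final cross-restart score comparison, so the reported
#' score is the score of the shipped unit.  Ties across restarts are broken
#' by restart index.
#'
#' @param value_fn `function(unit)` returning the scalar objective to
#'   maximise.
#' @param config a [design_config()].
#' @param frozen a list as from the Gibbs draw: `v`, `dt` (NA where free)
#'   and `free_mask`; `NULL` means all six scalars free.
#' @return a [design_unit()] with attributes `score` and `restart_scores`.
#' @export
optimise_unit <- function(value_fn, config, frozen = NULL) {
  if (is.null(frozen))
    frozen <- list(v = rep(NA_real_, 3), dt = rep(NA_real_, 3),
                   free_mask = rep(TRUE, 6))
  free <- frozen$free_mask
  lower <- c(rep(config$v_bounds[1], 3), rep(config$dt_bounds[1], 3))[free]
  upper <- c(rep(config$v_bounds[2], 3), rep(config$dt_bounds[2], 3))[free]
  build_unit <- function(x) {
    full <- c(frozen$v, frozen$dt)
    full[free] <- x
    design_unit(full[1:3], full[4:6], free_mask = free)
  }
  round_x <- function(x) {
    grid <- c(rep(config$rounding[["v"]], 3), rep(config$rounding[["dt"]], 3))[free]
    pmin(pmax(.round_to(x, grid), lower), upper)
  }
  best_unit <- NULL
  best_score <- -Inf
  restart_scores <- numeric(config$n_restarts)
  n_failed <- 0L
  for (r in seq_len(config$n_restarts)) {
    x0 <- stats::runif(length(lower), lower, upper)
    res <- tryCatch(
      cma_es(function(x) value_fn(build_unit(x)), x0, lower, upper,
             sigma0 = config$cma$sigma0, popsize = config$cma$popsize,
             maxiter = config$cma$maxiter, stop_tol = config$cma$stop_tol,
             maximize = TRUE),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      restart_scores[r] <- NA_real_
      next
    }
    xr <- round_x(res$par)
    sc <- as.numeric(value_fn(build_unit(xr)))
    restart_scores[r] <- sc
    if (sc > best_score) {
      best_score <- sc
      best_unit <- build_unit(xr)
    }
  }
  if (is.null(best_unit))
    stop("all ", config$n_restarts, " restarts failed to evaluate (",
         n_failed, " errors)")
  attr(best_unit, "score") <- best_score
  attr(best_unit, "restart_scores") <- restart_scores
  best_unit
}

#' Iterative three-step protocol design
#'
#' Builds a `3 * n_units`-step protocol body unit by unit: unit `i` is
#' optimised (by [optimise_unit()]) conditional on the common head plus all
#' previously accepted units, under the configured objective.  For the
#' per-parameter objectives (`local_sens`, `sobol`) unit `i` targets
#' parameter `i`.  The final protocol is head + body + tail.  Fully
#' reproducible from `config$seed`.
#'
#' @param config a [design_config()].
#' @return an object of class `design_result`: list with `protocol` (full,
#'   head + body + tail), `body`, `units`, `unit_scores`, `config`.
#' @export
iterative_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  engine <- .make_engine(config)
  state <- engine$init()
  set.seed(config$seed)
  units <- vector("list", config$n_units)
  scores <- numeric(config$n_units)
  for (i in seq_len(config$n_units)) {
    frozen <- .gibbs_draw(config, i)
    unit <- optimise_unit(function(u) engine$value(u, state, i), config,
                          frozen = frozen)
    units[[i]] <- unit
    scores[i] <- attr(unit, "score")
    state <- engine$accept(unit, state)
  }
  body <- clamp_protocol(
    do.call(rbind, lapply(units, function(u) .unit_to_protocol(u)$segments)),
    name = paste0(config$objective, "_body"))
  full <- wrap_with_common(body, name = paste0(config$objective, "_design"))
  structure(list(protocol = full, body = body, units = units,
                 unit_scores = scores, config = config,
                 engine_samples = engine$samples),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Design result (objective '", x$config$objective, "', model '",
      x$config$model$name, "'): ", length(x$units), " units, ",
      n_commands(x$protocol), " total commands\n", sep = "")
  cat("  per-unit scores:", paste(signif(x$unit_scores, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Re-score a design result from scratch
#'
#' Recomputes every per-unit objective value of a [iterative_design()] result
#' using the public objective functions on the final (rounded, exported)
#' protocol, guarding against rounding or bookkeeping drift between the
#' optimiser's internal scoring and the shipped protocol.
#'
#' @param result a `design_result`.
#' @return numeric vector of re-evaluated per-unit scores.
#' @export
score_design <- function(result) {
  stopifnot(inherits(result, "design_result"))
  config <- result$config
  model <- config$model
  context <- common_head()
  out <- numeric(length(result$units))
  for (i in seq_along(result$units)) {
    unit <- result$units[[i]]
    out[i] <- switch(config$objective,
      spacefill = phase_coverage_objective(unit, context, model,
                                           grid = config$grid,
                                           dt_out = config$dt_out),
      discrim = model_discrimination_objective(unit, context, model,
                                               config$model_b,
                                               dt_out = config$dt_out),
      brute_rmsd = brute_force_spread_objective(unit, context, model,
                                                result$engine_samples,
                                                dt_out = config$dt_out),
      local_sens = as.numeric(local_sensitivity_objective(
        i, unit, context, model, dt_out = config$dt_out)),
      sobol = as.numeric(sobol_first_order_objective(
        i, unit, context, model, n_base = config$n_base,
        seed = config$seed, dt_out = config$dt_out)))
    context <- concat_protocols(context, .unit_to_protocol(unit))
  }
  out
}

#' Space-filling design with multiple optimisation runs
#'
#' Runs the phase-voltage space-filling iterative designer `n_runs` times
#' with different random seeds (`config$seed + run - 1`), then selects the
#' best run under each of three criteria: (1) the best space-filling score
#' (total boxes visited by the full protocol); (2) the largest RMSD between
#' the two models' simulated currents; (3) the best sampled-parameter spread
#' score ([pairwise_rmsd_spread()]) for the design model.  Ties are broken
#' by run index.
#'
#' @param config a [design_config()] with `objective = "spacefill"`.
#' @param n_runs number of optimisation runs (>= 1).
#' @param model_b second model for criterion 2 (default: the five-state
#'   model).
#' @return an object of class `spacefill_runs`: list with `runs` (the
#'   [iterative_design()] results), `metrics` (data frame with columns
#'   `run`, `seed`, `coverage`, `discrim_rmsd`, `spread`), `selection`
#'   (named run indices `best_coverage`, `best_discrim`, `best_spread`).
#' @export
spacefill_design <- function(config, n_runs = 5L, model_b = wang_model()) {
  stopifnot(inherits(config, "design_config"), n_runs >= 1)
  if (config$objective != "spacefill")
    stop("spacefill_design() requires objective = 'spacefill'")
  runs <- vector("list", n_runs)
  metrics <- data.frame(run = seq_len(n_runs), seed = NA_integer_,
                        coverage = NA_real_, discrim_rmsd = NA_real_,
                        spread = NA_real_)
  ranges <- if (config$model$name == "wang") wang_ranges() else beattie_ranges()
  samples <- sample_parameters(ranges, config$M, scale = config$sample_scale,
                               seed = config$seed)
  for (k in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    runs[[k]] <- iterative_design(cfg)
    full <- runs[[k]]$protocol
    metrics$seed[k] <- cfg$seed
    metrics$coverage[k] <- protocol_phase_coverage(full, config$model,
                                                   grid = config$grid,
                                                   dt_out = config$dt_out)
    sa <- simulate_current(config$model, full, dt_out = config$dt_out,
                           e_rev = config$e_rev)
    sb <- simulate_current(model_b, full, dt_out = config$dt_out,
                           e_rev = config$e_rev)
    metrics$discrim_rmsd[k] <- rmsd(sa$current, sb$current)
    traces <- t(apply(samples$samples, 1, function(row) {
      pp <- config$model$params
      pp$values[colnames(samples$samples)] <- row
      simulate_current(.model_with_params(config$model, pp), full,
                       dt_out = config$dt_out, e_rev = config$e_rev)$current
    }))
    metrics$spread[k] <- pairwise_rmsd_spread(traces)
  }
  selection <- c(best_coverage = which.max(metrics$coverage),
                 best_discrim = which.max(metrics$discrim_rmsd),
                 best_spread = which.max(metrics$spread))
  structure(list(runs = runs, metrics = metrics, selection = selection),
            class = "spacefill_runs")
}

#' @export
print.spacefill_runs <- function(x, ...) {
  cat("Space-filling design:", nrow(x$metrics), "run(s)\n")
  print(x$metrics)
  cat("selected runs:", paste(names(x$selection), x$selection,
                              collapse = "; "), "\n")
  invisible(x)
}

#' Total phase-voltage coverage of a protocol
#'
#' Number of distinct phase-grid boxes visited by the four-state model's
#' `(a, r, V)` trajectory over an entire protocol (head and tail included),
#' sampled at `dt_out`.
#'
#' @param protocol a [clamp_protocol()].
#' @param model the four-state [gating_model()].
#' @param grid a [phase_grid()].
#' @param dt_out sampling interval (ms).
#' @return integer box count (at most `grid$n_boxes`).
#' @export
protocol_phase_coverage <- function(protocol, model = beattie_model(),
                                    grid = phase_grid(), dt_out = 1) {
  tr <- hh_trajectory(protocol, model$params, dt_out = dt_out)
  length(phase_coverage(tr, grid)$visited)
}

#' Square-wave two-model discrimination design
#'
#' Optimises the nine parameters of a three-component square-wave protocol
#' (amplitudes, angular frequencies, phases; offset fixed at -30 mV) to
#' maximise the RMSD between the currents of two candidate models at their
#' default parameters, by CMA-ES with restarts.  When one or more optimised
#' parameters land on a search bound a warning is emitted: bound-hitting
#' optima indicate ever-faster/larger voltage swings and are likely
#' impractical for real experiments.
#'
#' @param model_a,model_b the two candidate [gating_model()]s.
#' @param duration square-wave body duration (ms).
#' @param amp_bounds,omega_bounds,phase_bounds per-component bounds for
#'   amplitudes (mV), angular frequencies (rad/ms) and phases (rad).
#' @param offset fixed offset voltage (mV, default -30).
#' @param n_components number of square-wave components (default 3).
#' @param n_restarts,seed,maxiter optimisation settings.
#' @param dt_out,e_rev simulation settings.
#' @return an object of class `squarewave_design`: list with `spec` (the
#'   optimised [square_wave_spec()]), `score` (the RMSD), `protocol`
#'   (head + converted steps + tail), `boundary_hit` (logical),
#'   `restart_scores`.
#' @export
squarewave_discrimination_design <- function(model_a = beattie_model(),
                                             model_b = wang_model(),
                                             duration = 1000,
                                             amp_bounds = c(0.5, 60),
                                             omega_bounds = c(1e-3, 0.5),
                                             phase_bounds = c(0, 2 * pi),
                                             offset = -30,
                                             n_components = 3L,
                                             n_restarts = 3L, seed = 1L,
                                             maxiter = 60L, dt_out = 1,
                                             e_rev = -88) {
  nc <- as.integer(n_components)
  lower <- c(rep(amp_bounds[1], nc), rep(omega_bounds[1], nc),
             rep(phase_bounds[1], nc))
  upper <- c(rep(amp_bounds[2], nc), rep(omega_bounds[2], nc),
             rep(phase_bounds[2], nc))
  head <- common_head()
  xa0 <- simulate_current(model_a, head, dt_out = dt_out,
                          e_rev = e_rev)$final_state
  xb0 <- simulate_current(model_b, head, dt_out = dt_out,
                          e_rev = e_rev)$final_state
  off <- protocol_duration(head)
  value_fn <- function(x) {
    spec <- square_wave_spec(x[1:nc], x[nc + 1:nc], x[2 * nc + 1:nc],
                             b = offset)
    body <- square_wave_to_segments(spec, duration, max_segments = 100000L)
    segs <- body$segments
    t_cur <- off
    cur_a <- vector("list", nrow(segs)); cur_b <- cur_a
    xa <- xa0; xb <- xb0
    for (j in seq_len(nrow(segs))) {
      tl <- .grid_times(t_cur, segs$duration[j], dt_out) - t_cur
      Aa <- transition_matrix(model_a, segs$v_start[j])
      Ab <- transition_matrix(model_b, segs$v_start[j])
      ra <- .propagate_step(Aa, xa, segs$duration[j], tl)
      rb <- .propagate_step(Ab, xb, segs$duration[j], tl)
      cur_a[[j]] <- model_a$params$g * ra$states[, model_a$open_state] *
        (segs$v_start[j] - e_rev)
      cur_b[[j]] <- model_b$params$g * rb$states[, model_b$open_state] *
        (segs$v_start[j] - e_rev)
      xa <- ra$end; xb <- rb$end
      t_cur <- t_cur + segs$duration[j]
    }
    rmsd(unlist(cur_a), unlist(cur_b))
  }
  set.seed(seed)
  best <- NULL
  best_score <- -Inf
  restart_scores <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    x0 <- stats::runif(length(lower), lower, upper)
    res <- cma_es(value_fn, x0, lower, upper, maxiter = maxiter,
                  maximize = TRUE)
    restart_scores[r] <- res$value
    if (res$value > best_score) {
      best_score <- res$value
      best <- res$par
    }
  }
  tol <- 1e-6 * (upper - lower)
  boundary_hit <- any(best - lower <= tol | upper - best <= tol)
  if (boundary_hit)
    warning("optimised square-wave parameters lie on the search bounds; ",
            "the design favours extreme frequencies/amplitudes and is ",
            "likely impractical for real experiments")
  spec <- square_wave_spec(best[1:nc], best[nc + 1:nc], best[2 * nc + 1:nc],
                           b = offset)
  body <- square_wave_to_segments(spec, duration, max_segments = 100000L,
                                  name = "maxdiff_squarewave")
  structure(list(spec = spec, score = best_score,
                 protocol = wrap_with_common(body, name = "maxdiff"),
                 boundary_hit = boundary_hit,
                 restart_scores = restart_scores, seed = seed),
            class = "squarewave_design")
}

#' @export
print.squarewave_design <- function(x, ...) {
  cat("Square-wave discrimination design: score (RMSD) =",
      format(x$score, digits = 5), "\n")
  print(x$spec)
  if (x$boundary_hit)
    cat("NOTE: optimum lies on the parameter bounds (likely impractical)\n")
  invisible(x)
}
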