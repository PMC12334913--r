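#' Fit a gating model to an observed current trace
#'
#' Sum-of-squares fit: minimises the RMSD between the simulated and observed
#' current over the kinetic parameters (and, optionally, the conductance) by
#' CMA-ES on log-transformed parameters, restarted from multiplicatively
#' jittered versions of the supplied starting values.  The observed trace
#' must be aligned to the protocol's output grid at `dt_out`.
#'
#' @param model a [gating_model()] supplying the structure and the starting
#'   parameter values.
#' @param protocol the [clamp_protocol()] the data were recorded under.
#' @param observed numeric current trace on the `dt_out` grid of
#'   `simulate_current(model, protocol, dt_out = dt_out)`.
#' @param restarts number of optimisation restarts.
#' @param seed RNG seed.
#' @param fit_conductance also fit `g` (default `TRUE`).
#' @param fixed_kinetics hold the kinetic parameters at their starting
#'   values and fit only `g` (closed form: `g` scales the current
#'   linearly).
#' @param log_span half-width (in natural-log units) of the search box
#'   around the log starting values.
#' @param maxiter CMA-ES generations per restart.
#' @param dt_out,e_rev simulation settings (must match the data).
#' @return an object of class `clamp_fit` with methods [coef.clamp_fit()],
#'   `print`, `summary`, `residuals`, `fitted` and `predict`.
#' @export
fit_model <- function(model, protocol, observed, restarts = 1L, seed = 1L,
                      fit_conductance = TRUE, fixed_kinetics = FALSE,
                      log_span = 1.5, maxiter = 250L, dt_out = 1,
                      e_rev = -88) {
  stopifnot(inherits(model, "gating_model"), inherits(protocol, "clamp_protocol"))
  ref <- simulate_current(model, protocol, dt_out = dt_out, e_rev = e_rev)
  if (length(observed) != length(ref$times))
    stop("'observed' has ", length(observed), " samples but the protocol grid",
         " has ", length(ref$times))
  if (fixed_kinetics) {
    # I = g * q(t): least-squares g is <I_obs, q>/<q, q>, exact.
    q <- ref$current / model$params$g
    g_hat <- sum(observed * q) / sum(q * q)
    pars <- model$params
    pars$g <- g_hat
    fitted_cur <- g_hat * q
    return(structure(list(parameters = pars, rmsd = rmsd(fitted_cur, observed),
                          fitted = fitted_cur, observed = observed,
                          times = ref$times, model = model$name,
                          protocol = protocol$name, converged = TRUE,
                          restart_values = NA_real_, dt_out = dt_out,
                          e_rev = e_rev),
                     class = "clamp_fit"))
  }
  p0 <- model$params$values
  theta0 <- log(c(p0, if (fit_conductance) c(g = model$params$g)))
  lower <- theta0 - log_span
  upper <- theta0 + log_span
  make_params <- function(theta) {
    pp <- model$params
    pp$values <- exp(theta[seq_along(p0)])
    names(pp$values) <- names(p0)
    if (fit_conductance) pp$g <- exp(theta[[length(theta)]])
    pp
  }
  obj <- function(theta) {
    sim <- tryCatch(
      simulate_current(.model_with_params(model, make_params(theta)),
                       protocol, dt_out = dt_out, e_rev = e_rev),
      error = function(e) NULL)
    if (is.null(sim)) return(1e10)
    rmsd(sim$current, observed)
  }
  set.seed(seed)
  best <- NULL
  best_val <- Inf
  restart_values <- numeric(restarts)
  for (r in seq_len(restarts)) {
    x0 <- pmin(pmax(theta0 + stats::rnorm(length(theta0), 0, 0.25),
                    lower), upper)
    res <- cma_es(obj, x0, lower, upper, maxiter = maxiter,
                  stop_tol = 1e-10)
    restart_values[r] <- res$value
    if (res$value < best_val) {
      best_val <- res$value
      best <- res$par
    }
  }
  pars <- make_params(best)
  sim <- simulate_current(.model_with_params(model, pars), protocol,
                          dt_out = dt_out, e_rev = e_rev)
  structure(list(parameters = pars, rmsd = best_val, fitted = sim$current,
                 observed = observed, times = ref$times, model = model$name,
                 protocol = protocol$name,
                 converged = is.finite(best_val) && best_val < 1e10,
                 restart_values = restart_values, dt_out = dt_out,
                 e_rev = e_rev),
            class = "clamp_fit")
}

#' @export
print.clamp_fit <- function(x, ...) {
  cat("Gating-model fit ('", x$model, "' under '", x$protocol, "')\n",
      sep = "")
  cat("  RMSD =", format(x$rmsd, digits = 6), "(0.1 nA);",
      if (x$converged) "converged" else "NOT converged (best-so-far shown)",
      "\n")
  print(signif(coef(x), 4))
  invisible(x)
}

#' Extract fitted parameters
#' @param object a `clamp_fit`.
#' @param ... unused.
#' @return named vector of fitted kinetic parameters plus `g`.
#' @export
coef.clamp_fit <- function(object, ...) {
  c(object$parameters$values, g = object$parameters$g)
}

#' @export
summary.clamp_fit <- function(object, ...) {
  res <- residuals(object)
  cat("Gating-model fit summary\n")
  cat("  model:", object$model, " protocol:", object$protocol, "\n")
  cat("  n =", length(res), "samples at", object$dt_out, "ms\n")
  cat("  RMSD =", format(object$rmsd, digits = 6),
      " residual range [", format(min(res), digits = 4), ",",
      format(max(res), digits = 4), "]\n")
  print(signif(coef(object), 4))
  invisible(object)
}

#' @export
residuals.clamp_fit <- function(object, ...) object$observed - object$fitted

#' @export
fitted.clamp_fit <- function(object, ...) object$fitted

#' Predict the current under a (possibly new) protocol from a fit
#' @param object a `clamp_fit`.
#' @param protocol a [clamp_protocol()]; default: re-simulate the fitted
#'   protocol is not possible from the stored name, so a protocol must be
#'   given.
#' @param model a [gating_model()] of the fitted family.
#' @param ... unused.
#' @return a [simulate_current()] result under the fitted parameters.
#' @export
predict.clamp_fit <- function(object, protocol, model = NULL, ...) {
  if (is.null(model))
    model <- if (object$model == "wang") wang_model() else beattie_model()
  simulate_current(.model_with_params(model, object$parameters), protocol,
                   dt_out = object$dt_out, e_rev = object$e_rev)
}
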