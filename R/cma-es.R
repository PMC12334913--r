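#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Standard (mu/mu_w, lambda) CMA-ES for bound-constrained derivative-free
#' optimisation.  The search is carried out in the unit cube (coordinates
#' scaled to the bounds); candidates falling outside the box are clipped to
#' it and evaluated there (penalty-free).  Uses the current R RNG stream;
#' seed with `set.seed()` for reproducibility.
#'
#' Out-of-box candidates are repaired by clipping and evaluated at the
#' clipped (feasible) point; for selection their fitness is additionally
#' penalised by the squared repair distance (scaled to the current
#' generation's fitness spread), which prevents the search mass from
#' drifting outside the box when the optimum sits near a bound.  Reported
#' values are always the objective at the feasible point.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point (within bounds).
#' @param lower,upper bounds, same length as `x0`.
#' @param sigma0 initial step size as a fraction of each bound range
#'   (default 1/6).
#' @param popsize offspring per generation (default `4 + floor(3*log(n))`).
#' @param maxiter maximum generations.
#' @param stop_tol stop when the step size collapses below this fraction of
#'   the bound range, or the population fitness spread stagnates.
#' @param maximize maximise instead of minimise.
#' @return list with `par`, `value` (on the original objective scale),
#'   `evals`, `generations`.
#' @export
cma_es <- function(fn, x0, lower, upper, sigma0 = 1 / 6, popsize = NULL,
                   maxiter = 300L, stop_tol = 1e-8, maximize = FALSE) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(upper > lower))
  span <- upper - lower
  u0 <- (x0 - lower) / span
  f_int <- function(u) {
    v <- fn(lower + pmin(pmax(u, 0), 1) * span)
    if (maximize) -v else v
  }
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- u0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  eig <- list(values = rep(1, n), vectors = diag(n))
  best_u <- pmin(pmax(u0, 0), 1)
  best_f <- f_int(u0)
  evals <- 1L
  gen <- 0L
  while (gen < maxiter) {
    gen <- gen + 1L
    BD <- eig$vectors %*% diag(sqrt(pmax(eig$values, 1e-20)), n)
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    arx <- xmean + sigma * (BD %*% arz)
    arx_clip <- pmin(pmax(arx, 0), 1)
    fvals <- apply(arx_clip, 2, f_int)
    evals <- evals + lambda
    # selection fitness: objective at the repaired point plus a repair
    # penalty scaled to the generation's fitness spread
    dist2 <- colSums((arx - arx_clip)^2)
    pen <- (diff(range(fvals)) + 1e-8) * dist2
    rankv <- fvals + pen
    ord <- order(rankv)
    ibest <- which.min(fvals)
    if (fvals[ibest] < best_f) {
      best_f <- fvals[ibest]
      best_u <- arx_clip[, ibest]
    }
    sel <- ord[seq_len(mu)]
    zmean <- arz[, sel, drop = FALSE] %*% w
    xmean <- as.numeric(xmean + sigma * (BD %*% zmean))
    ps <- as.numeric((1 - cs) * ps +
    sqrt(cs * (2 - cs) * mueff) * (eig$vectors %*% zmean))
    hsig <- as.numeric(sqrt(sum(ps^2)) /
                         sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
                         1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * as.numeric(BD %*% zmean)
    artmp <- BD %*% arz[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% diag(w, mu) %*% t(artmp)
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    if (any(eig$values <= 0) || !all(is.finite(C))) {  # numerical reset
      C <- diag(n); eig <- list(values = rep(1, n), vectors = diag(n))
      pc <- ps <- numeric(n)
    }
    if (sigma * sqrt(max(eig$values)) < stop_tol) break
    if (diff(range(rankv)) == 0 && sigma < 1e-4) break
  }
  list(par = lower + best_u * span,
       value = if (maximize) -best_f else best_f,
       evals = evals, generations = gen)
}
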