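# ---- elementary gap-time draws -------------------------------------------

# Inverse-survival transform for the Weibull proportional-hazards gap:
# S(t) = exp(-lambda t^p e^{beta Z + u}) evaluated at survival prob U.
qgap_weibull <- function(U, u, Z, lambda, p, beta) {
  (-log(U) / (lambda * exp(beta * Z + u)))^(1 / p)
}

#' Draw Weibull proportional-hazards gap times
#'
#' Gap times with survival function
#' \eqn{S(\tilde t) = \exp(-\lambda \tilde t^{\,p} e^{\beta Z + u})},
#' drawn by the inversion method: \eqn{\tilde t = (-\ln U / (\lambda
#' e^{\beta Z + u}))^{1/p}} with \eqn{U \sim U(0,1)}.
#'
#' @param n number of draws.
#' @param u frailty value(s) on the log-hazard scale (length 1 or `n`).
#' @param Z binary covariate value(s).
#' @param lambda,p Weibull scale and shape, both positive.
#' @param beta covariate coefficient.
#' @return numeric vector of `n` gap times (years).
#' @export
draw_weibull_gap <- function(n, u, Z, lambda, p, beta = 0) {
  stopifnot(lambda > 0, p > 0)
  if (any(!is.finite(u))) stop("non-finite frailty value 'u'")
  qgap_weibull(stats::runif(n), u, Z, lambda, p, beta)
}

# ---- chunked renewal engine ----------------------------------------------

# Visit times for n individuals whose gaps are iid given the individual.
# C: censoring times; rgap(idx, m): [m x length(idx)] matrix of gaps.
# Returns a list of per-individual visit-time vectors (baseline excluded).
sim_iid_visit_times <- function(C, rgap, chunk = 16L) {
  n <- length(C)
  times <- vector("list", n)
  last <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    g <- rgap(active, chunk)
    if (!is.matrix(g)) g <- matrix(g, nrow = chunk)
    ct <- matrix(apply(g, 2L, cumsum), nrow = chunk) +
      rep(last[active], each = chunk)
    keep <- logical(length(active))
    for (k in seq_along(active)) {
      i <- active[k]
      ok <- ct[, k] <= C[i]
      if (all(ok)) {
        times[[i]] <- c(times[[i]], ct[, k])
        last[i] <- ct[chunk, k]
        keep[k] <- TRUE
      } else {
        nf <- which(!ok)[1L] - 1L
        if (nf > 0L) times[[i]] <- c(times[[i]], ct[seq_len(nf), k])
      }
    }
    active <- active[keep]
  }
  times
}

# Assemble the long-format panel from per-individual visit times.
# mean_y(i, t): vector of outcome means for individual i at times t.
build_panel <- function(visit_times, Z, C, mean_y, sigma2_eps, latents) {
  n <- length(C)
  n_obs <- vapply(visit_times, length, 1L) + 1L   # + baseline
  rows <- n_obs + 1L                              # + censored gap row
  id <- rep.int(seq_len(n), rows)
  t <- unlist(lapply(seq_len(n), function(i)
    c(0, visit_times[[i]], C[i])), use.names = FALSE)
  j <- unlist(lapply(rows, function(r) 0:(r - 1L)), use.names = FALSE)
  gap <- unlist(lapply(seq_len(n), function(i)
    c(0, diff(c(0, visit_times[[i]], C[i])))), use.names = FALSE)
  d <- unlist(lapply(rows, function(r) c(rep.int(1L, r - 1L), 0L)),
              use.names = FALSE)
  obs <- d == 1L
  y <- rep(NA_real_, length(id))
  mu <- unlist(lapply(seq_len(n), function(i)
    mean_y(i, c(0, visit_times[[i]]))), use.names = FALSE)
  y[obs] <- mu + stats::rnorm(sum(obs), 0, sqrt(sigma2_eps))
  visit_panel(data.frame(id = id, j = j, t = t, gap = gap, d = d,
                         y = y, Z = rep.int(Z, rows),
                         C = rep.int(C, rows)),
              latents = latents)
}

# ---- DGM-specific simulators ---------------------------------------------

simulate_joint_scenario <- function(cfg) {
  stopifnot(cfg$dgm %in% c("joint", "joint_regular_visits"))
  n <- cfg$n_individuals
  Z <- stats::rbinom(n, 1, cfg$treatment_prob)
  u <- stats::rnorm(n, 0, sqrt(cfg$sigma2_u))
  v <- stats::rnorm(n, 0, sqrt(cfg$sigma2_v))
  C <- stats::runif(n, cfg$censor_lo, cfg$censor_hi)
  rate <- cfg$lambda * exp(cfg$beta * Z + u)
  rgap <- function(idx, m) {
    k <- length(idx)
    matrix((-log(stats::runif(m * k)) /
              rep(rate[idx], each = m))^(1 / cfg$p), nrow = m)
  }
  vt <- sim_iid_visit_times(C, rgap)
  if (cfg$dgm == "joint_regular_visits") {
    # Planned visits are exogenous interruptions: merged into the schedule
    # without resetting the frailty-driven gap clock.
    vt <- lapply(seq_len(n), function(i) {
      planned <- seq(cfg$regular_interval, C[i], by = cfg$regular_interval)
      sort(unique(c(vt[[i]], planned)))
    })
  }
  mean_y <- function(i, t)
    cfg$alpha0 + Z[i] * cfg$alpha1 + t * cfg$alpha2 +
      cfg$gamma_assoc * u[i] + v[i]
  build_panel(vt, Z, C, mean_y, cfg$sigma2_eps,
              latents = data.frame(id = seq_len(n), u = u, v = v,
                                   xi = NA_real_))
}

simulate_gamma_scenario <- function(cfg) {
  stopifnot(cfg$dgm %in% c("gamma", "gamma_lagged_y"))
  if (cfg$dgm == "gamma_lagged_y" && is.null(cfg$omega))
    stop("'omega' must be supplied for the lagged-outcome Gamma DGM")
  n <- cfg$n_individuals
  Z <- stats::rbinom(n, 1, cfg$treatment_prob)
  v <- stats::rnorm(n, 0, sqrt(cfg$sigma2_v))
  xi <- stats::rnorm(n, 0, sqrt(cfg$sigma2_xi))
  C <- stats::runif(n, cfg$censor_lo, cfg$censor_hi)
  latents <- data.frame(id = seq_len(n), u = NA_real_, v = v, xi = xi)
  mean_y <- function(i, t)
    cfg$alpha0 + Z[i] * cfg$alpha1 + t * cfg$alpha2 + v[i]

  if (cfg$dgm == "gamma") {
    scale <- exp(-cfg$psi * cfg$beta * Z + xi)
    rgap <- function(idx, m) {
      k <- length(idx)
      matrix(stats::rgamma(m * k, shape = cfg$gamma_shape,
                           scale = rep(scale[idx], each = m)), nrow = m)
    }
    vt <- sim_iid_visit_times(C, rgap)
    return(build_panel(vt, Z, C, mean_y, cfg$sigma2_eps, latents))
  }

  # Lagged-outcome variant: the scale of each gap depends on the outcome
  # recorded at the previous visit, so gaps and outcomes are generated
  # jointly, one visit round at a time across all active individuals.
  times <- vector("list", n)
  ys <- vector("list", n)
  y_prev <- mean_y(seq_len(n), 0) + stats::rnorm(n, 0, sqrt(cfg$sigma2_eps))
  y0 <- y_prev
  last <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    sc <- exp(-cfg$psi * cfg$beta * Z[active] +
                cfg$omega * y_prev[active] + xi[active])
    g <- stats::rgamma(length(active), shape = cfg$gamma_shape, scale = sc)
    t_new <- last[active] + g
    ok <- t_new <= C[active]
    ii <- active[ok]
    if (length(ii)) {
      y_new <- mean_y(ii, t_new[ok]) +
        stats::rnorm(length(ii), 0, sqrt(cfg$sigma2_eps))
      for (k in seq_along(ii)) {
        i <- ii[k]
        times[[i]] <- c(times[[i]], t_new[ok][k])
        ys[[i]] <- c(ys[[i]], y_new[k])
      }
      last[ii] <- t_new[ok]
      y_prev[ii] <- y_new
    }
    active <- active[ok]
  }
  # Outcomes were generated alongside the visit times; reuse them.
  panel <- build_panel(times, Z, C, mean_y, cfg$sigma2_eps, latents)
  obs <- panel$d == 1L
  panel$y[obs] <- unlist(lapply(seq_len(n), function(i)
    c(y0[i], ys[[i]])), use.names = FALSE)
  panel
}

#' Simulate datasets from a scenario
#'
#' Generates long-format visit panels under the scenario's
#' data-generating mechanism. Individuals are followed from a
#' deterministic baseline visit at t = 0 until administrative censoring;
#' the final row of each individual is the censored terminal gap.
#'
#' @param object a [visit_scenario()].
#' @param nsim number of datasets.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param ... unused.
#' @return a [visit_panel()] when `nsim = 1`, otherwise a list of them.
#' @examples
#' sc <- visit_scenario("gamma", psi = 2, n_individuals = 50)
#' summary(simulate(sc, seed = 42))
#' @export
simulate.visit_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    if (object$dgm %in% c("joint", "joint_regular_visits"))
      simulate_joint_scenario(object)
    else
      simulate_gamma_scenario(object)
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}
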