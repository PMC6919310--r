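# Joint model: Weibull gap-time visiting process and Gaussian
# longitudinal outcome linked by a shared random intercept u.
#
#   r(t~_ij | Z_i, u_i) = lambda p t~^(p-1) exp(beta Z_i + u_i)
#   y_ij = alpha0 + Z_i alpha1 + t_ij alpha2 + gamma u_i + v_i + e_ij
#
# The marginal likelihood integrates out (u_i, v_i). The v-integral is
# Gaussian with compound-symmetry covariance and has a closed form, so
# only the u-integral is evaluated numerically (adaptive Gauss-Hermite).

jm_par_names <- c("lambda", "p", "beta", "alpha0", "alpha1", "alpha2",
                  "gamma", "sigma2_u", "sigma2_v", "sigma2_eps")

# Per-individual sufficient statistics that do not depend on parameters.
jm_stats <- function(data) {
  id <- factor(data$id, levels = unique(data$id))
  gaps <- data$j > 0               # rows carrying a gap-time contribution
  obs <- data$d == 1 & !is.na(data$y)
  idg <- droplevels(id[gaps])
  ido <- droplevels(id[obs])
  lev <- levels(id)
  zero <- stats::setNames(numeric(length(lev)), lev)
  acc <- function(x, f) {
    out <- zero
    s <- rowsum(x, f)
    out[rownames(s)] <- s
    out
  }
  list(lev = lev,
       Z = data$Z[!duplicated(data$id)],
       # gap rows (integer group codes into lev for fast rowsum)
       tg = data$gap[gaps], dg = data$d[gaps],
       log_tg = log(data$gap[gaps]), idg = idg,
       gg = match(as.character(idg), lev),
       D = acc(data$d[gaps], idg),
       sum_logt_ev = acc(ifelse(data$d[gaps] == 1,
                                log(data$gap[gaps]), 0), idg),
       # outcome rows
       yo = data$y[obs], to = data$t[obs], Zo = data$Z[obs], ido = ido,
       go = match(as.character(ido), lev),
       n_obs = acc(rep(1, sum(obs)), ido))
}

row_maxes <- function(M) {
  m <- M[, 1L]
  for (k in seq_len(ncol(M))[-1L]) m <- pmax(m, M[, k])
  m
}

jm_check_params <- function(par) {
  par <- unlist(par)[jm_par_names]
  if (anyNA(par)) stop("params must contain: ",
                       paste(jm_par_names, collapse = ", "))
  if (par["lambda"] <= 0 || par["p"] <= 0 || par["sigma2_eps"] <= 0)
    stop("lambda, p and sigma2_eps must be strictly positive")
  if (par["sigma2_u"] < 0 || par["sigma2_v"] < 0)
    stop("variances must be non-negative")
  par
}

# Coefficients of the per-individual log-integrand in u:
#   h_i(u) = k0_i + D_i u - w0_i e^u + b_i u + c_i u^2 + log phi(u; 0, s2u)
jm_integrand_coefs <- function(par, st) {
  lambda <- par["lambda"]; p <- par["p"]; beta <- par["beta"]
  g <- par["gamma"]; s2v <- par["sigma2_v"]; s2e <- par["sigma2_eps"]
  nlev <- length(st$lev)
  acc_int <- function(x, g) {
    out <- numeric(nlev)
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s
    out
  }
  S <- acc_int(exp(p * st$log_tg), st$gg)
  # Weibull events part
  k_weib <- st$D * (log(lambda * p) + beta * st$Z) +
    (p - 1) * st$sum_logt_ev
  w0 <- lambda * exp(beta * st$Z) * S
  # outcome part: residual sums given the fixed effects
  r <- st$yo - (par["alpha0"] + par["alpha1"] * st$Zo + par["alpha2"] * st$to)
  Sr <- acc_int(r, st$go)
  Sr2 <- acc_int(r^2, st$go)
  n <- st$n_obs
  denom <- s2e + n * s2v
  kk <- s2v / denom                       # shrinkage factor
  w <- s2e / denom                        # 1 - n*kk
  a <- -0.5 * (n * log(2 * pi) + (n - 1) * log(s2e) + log(denom)) -
    (Sr2 - kk * Sr^2) / (2 * s2e)
  b <- g * Sr * w / s2e
  cc <- -g^2 * n * w / (2 * s2e)
  list(k0 = k_weib + a, D = st$D, w0 = w0, b = b, cc = cc)
}

# Vectorised Newton search for the mode of the (strictly concave)
# per-individual log-integrand including the N(0, s2u) prior.
jm_find_modes <- function(cf, s2u, tol = 1e-10, maxit = 50L) {
  u <- numeric(length(cf$D))
  for (it in seq_len(maxit)) {
    eu <- exp(u)
    g1 <- cf$D - cf$w0 * eu + cf$b + 2 * cf$cc * u - u / s2u
    g2 <- -cf$w0 * eu + 2 * cf$cc - 1 / s2u
    step <- g1 / g2
    step <- pmax(pmin(step, 2), -2)
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  list(u = u, h2 = -cf$w0 * exp(u) + 2 * cf$cc - 1 / s2u)
}

#' Marginal log-likelihood of the joint visiting-outcome model
#'
#' Evaluates the log-likelihood with the random effects integrated out:
#' the outcome random intercept analytically (its conditional
#' contribution is Gaussian with compound-symmetry covariance) and the
#' shared random effect by Gauss-Hermite quadrature, adaptively centred
#' and scaled at each individual's posterior mode by default.
#'
#' @param params named vector or list with elements `lambda`, `p`,
#'   `beta`, `alpha0`, `alpha1`, `alpha2`, `gamma`, `sigma2_u`,
#'   `sigma2_v`, `sigma2_eps`.
#' @param data a [visit_panel()] (or coercible data frame).
#' @param n_quad quadrature nodes for the shared-effect integral.
#' @param adaptive centre and scale nodes per individual (recommended);
#'   otherwise a dense rule on the prior scale is used.
#' @param validate check panel invariants first.
#' @return the log-likelihood (a scalar); an error is raised if the
#'   quadrature yields a non-finite value.
#' @export
joint_loglik <- function(params, data, n_quad = 9L, adaptive = TRUE,
                         validate = TRUE) {
  stopifnot(n_quad >= 3L)
  par <- jm_check_params(params)
  if (validate) validate_panel(data)
  st <- if (inherits(data, "jm_stats_cache")) data else jm_stats(data)
  ll <- jm_loglik_stats(par, st, n_quad, adaptive)
  if (!is.finite(ll)) stop("quadrature produced a non-finite log-likelihood")
  ll
}

jm_loglik_stats <- function(par, st, n_quad, adaptive) {
  cf <- jm_integrand_coefs(par, st)
  s2u <- par["sigma2_u"]
  if (s2u < 1e-12) {    # degenerate prior: point mass at u = 0
    return(sum(cf$k0 - cf$w0))
  }
  rule <- gauss_hermite(n_quad)
  x <- rule$nodes; w <- rule$weights
  h <- function(u) {    # matrix of log-integrand values, indiv x nodes
    cf$k0 + cf$D * u - cf$w0 * exp(u) + cf$b * u + cf$cc * u^2 -
      u^2 / (2 * s2u) - 0.5 * log(2 * pi * s2u)
  }
  if (adaptive) {
    md <- jm_find_modes(cf, s2u)
    sig <- 1 / sqrt(-md$h2)
    U <- outer(sig, x * sqrt(2), `*`) + md$u      # indiv x nodes
    H <- h(U) + matrix(x^2, nrow(U), length(x), byrow = TRUE)
    m <- row_maxes(H)
    sum(log(sqrt(2) * sig) + m +
          log(rowSums(exp(H - m) *
                        matrix(w, nrow(U), length(w), byrow = TRUE))))
  } else {
    u <- sqrt(2 * s2u) * x
    U <- matrix(u, length(cf$D), length(u), byrow = TRUE)
    # prior already in h(); undo it and use the GH weight instead
    H <- h(U) + matrix(u^2 / (2 * s2u) + 0.5 * log(2 * pi * s2u),
                       length(cf$D), length(u), byrow = TRUE)
    m <- row_maxes(H)
    sum(m + log((exp(H - m) %*% w) / sqrt(pi)))
  }
}

# transformed <-> natural parameter scales (positives on the log scale)
jm_to_natural <- function(theta) {
  stats::setNames(c(exp(theta[1:2]), theta[3:7], exp(theta[8:10])),
                  jm_par_names)
}
jm_to_transformed <- function(par) {
  c(log(par[1:2]), par[3:7], log(par[8:10]))
}

# Severed-model starting values: Weibull recurrent-event fit ignoring
# the frailty (survreg AFT, converted to PH scale) + plain ML mixed model.
jm_start_values <- function(data, st) {
  gaps <- data.frame(gap = st$tg, d = st$dg,
                     Z = st$Z[match(as.character(st$idg), st$lev)])
  wb <- tryCatch({
    f <- survival::survreg(survival::Surv(gap, d) ~ Z, data = gaps,
                           dist = "weibull")
    p <- 1 / f$scale
    c(lambda = exp(-unname(stats::coef(f)[1]) * p),
      p = p, beta = -unname(stats::coef(f)[2]) * p)
  }, error = function(e) c(lambda = 0.5, p = 1, beta = 0))
  lm0 <- fit_lmm(data, adjustment = "none")
  cf <- stats::coef(lm0)
  c(lambda = unname(wb["lambda"]), p = unname(wb["p"]),
    beta = unname(wb["beta"]),
    alpha0 = unname(cf["alpha0"]), alpha1 = unname(cf["alpha1"]),
    alpha2 = unname(cf["alpha2"]),
    gamma = 0,
    sigma2_u = 0.5,
    sigma2_v = max(unname(cf["sigma2_v"]), 1e-3),
    sigma2_eps = max(unname(cf["sigma2_eps"]), 1e-3))
}

#' Fit the joint model by maximum likelihood (Model A)
#'
#' Maximises [joint_loglik()] over an unconstrained parameterisation
#' (positives on the log scale) with a quasi-Newton optimiser and
#' numerically differenced gradients. Starting values come from the
#' severed model: a Weibull recurrent-event fit that ignores the frailty
#' plus a plain random-intercept mixed model, with the association
#' started at zero. Standard errors are obtained from the inverse of the
#' numerically differentiated observed information, mapped to the
#' natural scale by the delta method.
#'
#' @param data a [visit_panel()].
#' @param n_quad quadrature nodes per shared-effect integral.
#' @param adaptive use adaptive (mode-centred) quadrature.
#' @param start optional named vector of natural-scale starting values.
#' @param control list: `maxit` (default 400), `reltol` (1e-10),
#'   `grad_tol` (gradient max-norm tolerance, scaled by max(1, |loglik|)
#'   x 1e-4).
#' @return a `visit_jm_fit` / [`visit_fit`][new_visit_fit] with natural-
#'   scale estimates `lambda, p, beta, alpha0, alpha1, alpha2, gamma,
#'   sigma2_u, sigma2_v, sigma2_eps`. Optimisation failures are reported
#'   through `converged = FALSE`, never as an error.
#' @examples
#' sc <- visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
#'                      n_individuals = 60)
#' fit <- fit_joint_model(simulate(sc, seed = 7))
#' summary(fit)
#' @export
fit_joint_model <- function(data, n_quad = 9L, adaptive = TRUE,
                            start = NULL, control = list()) {
  ctl <- utils::modifyList(list(maxit = 400L, reltol = 1e-10,
                                grad_tol = 1e-4), control)
  data <- as_visit_panel(data)
  st <- jm_stats(data)
  fail <- function(msg) {
    nav <- stats::setNames(rep(NA_real_, length(jm_par_names)),
                           jm_par_names)
    new_visit_fit("A", nav, nav, vcov = NULL, loglik = NA_real_,
                  converged = FALSE, n_quad = n_quad, message = msg,
                  class = "visit_jm_fit")
  }
  out <- tryCatch({
    if (is.null(start)) start <- jm_start_values(data, st)
    theta0 <- jm_to_transformed(jm_check_params(start))
    negll <- function(theta) {
      v <- tryCatch(
        -jm_loglik_stats(jm_to_natural(theta), st, n_quad, adaptive),
        error = function(e) Inf)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::optim(theta0, negll, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol,
                                       ndeps = rep(1e-5, length(theta0))))
    theta <- opt$par
    par <- jm_to_natural(theta)
    H <- pracma::hessian(negll, theta)
    pd <- all(is.finite(H)) &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
    gr <- pracma::grad(negll, theta)
    gtol <- ctl$grad_tol * max(1, abs(opt$value))
    conv <- (opt$convergence == 0) && pd && max(abs(gr)) < gtol
    if (pd) {
      vc_t <- solve(H)
      J <- diag(c(par[1:2], 1, 1, 1, 1, 1, par[8:10]))
      vc <- J %*% vc_t %*% t(J)
      dimnames(vc) <- list(jm_par_names, jm_par_names)
      se <- sqrt(pmax(diag(vc), 0))
    } else {
      vc <- NULL
      se <- rep(NA_real_, length(par))
    }
    new_visit_fit("A", par, stats::setNames(se, jm_par_names), vcov = vc,
                  loglik = -opt$value, converged = conv,
                  n_quad = n_quad, iterations = unname(opt$counts[1]),
                  grad_norm = max(abs(gr)), start = start,
                  class = "visit_jm_fit")
  }, error = function(e) fail(conditionMessage(e)))
  out
}
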