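#' Define a simulation scenario
#'
#' A scenario bundles every parameter of one data-generating mechanism
#' (DGM) for the visiting process and the longitudinal outcome. Four
#' DGMs are available:
#'
#' * `"joint"` — visits arise from a Weibull gap-time proportional-hazards
#'   process with hazard \eqn{r(\tilde t) = \lambda p \tilde t^{p-1}
#'   e^{\beta Z_i + u_i}}, and the outcome at each visit is
#'   \eqn{y_{ij} = \alpha_0 + Z_i\alpha_1 + t_{ij}\alpha_2 + \gamma u_i +
#'   v_i + \epsilon_{ij}}. The shared random intercept \eqn{u_i} makes the
#'   visiting process informative whenever \eqn{\gamma \neq 0}.
#' * `"joint_regular_visits"` — as `"joint"`, with planned visits at
#'   `regular_interval`, `2*regular_interval`, ... merged into each
#'   individual's schedule (outcomes at planned visits follow the same
#'   outcome equation).
#' * `"gamma"` — gap times drawn from a Gamma distribution with shape
#'   `gamma_shape` and scale \eqn{\exp(-\psi\beta Z_i + \xi_i)},
#'   \eqn{\xi_i \sim N(0, \sigma^2_\xi)}; the outcome has no shared
#'   effect (informative through treatment only, via \eqn{\psi}).
#' * `"gamma_lagged_y"` — as `"gamma"` with scale
#'   \eqn{\exp(-\psi\beta Z_i + \omega y_{i,j-1} + \xi_i)}, so the visit
#'   intensity responds to the last recorded outcome.
#'
#' Every individual is observed at baseline (t = 0) and followed until an
#' administrative censoring time \eqn{C_i \sim U(censor_lo, censor_hi)};
#' the final, censored gap runs from the last observation to \eqn{C_i}.
#'
#' Defaults are the reference study conditions: n = 200 individuals,
#' Weibull shape 1.05, treatment effect 1 on the visit process,
#' longitudinal fixed effects (0, 1, 0.2), variances
#' \eqn{\sigma^2_u = 1}, \eqn{\sigma^2_v = 0.5},
#' \eqn{\sigma^2_\epsilon = 1}, Gamma shape 2, \eqn{\sigma^2_\xi = 0.1},
#' \eqn{\omega = 0.2}, censoring U(5, 10), yearly planned visits.
#'
#' @param dgm one of `"joint"`, `"joint_regular_visits"`, `"gamma"`,
#'   `"gamma_lagged_y"`.
#' @param n_individuals number of individuals per dataset.
#' @param lambda,p Weibull scale and shape of the baseline visit hazard
#'   (joint DGMs).
#' @param beta treatment coefficient in the visit process.
#' @param alpha0,alpha1,alpha2 longitudinal fixed effects: intercept,
#'   treatment, time (per year).
#' @param gamma_assoc association parameter linking the shared random
#'   effect to the outcome (joint DGMs).
#' @param sigma2_u,sigma2_v,sigma2_eps variances of the shared random
#'   effect, the outcome random intercept, and the residual error.
#' @param psi treatment association of the Gamma visiting process.
#' @param omega lagged-outcome coefficient (`"gamma_lagged_y"` only).
#' @param sigma2_xi variance of the individual Gamma-scale effect.
#' @param gamma_shape shape of the Gamma gap-time distribution.
#' @param censor_lo,censor_hi bounds (years) of the uniform
#'   administrative censoring time.
#' @param regular_interval spacing (years) of planned visits
#'   (`"joint_regular_visits"` only).
#' @param treatment_prob Bernoulli probability of treatment assignment.
#' @return an object of class `visit_scenario` (a validated list of the
#'   above fields).
#' @seealso [simulate.visit_scenario()], [read_scenario()],
#'   [scenario_presets()]
#' @examples
#' sc <- visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3)
#' dat <- simulate(sc, seed = 1)
#' head(dat)
#' @export
visit_scenario <- function(dgm = c("joint", "joint_regular_visits",
                                   "gamma", "gamma_lagged_y"),
                           n_individuals = 200L,
                           lambda = 0.10, p = 1.05, beta = 1,
                           alpha0 = 0, alpha1 = 1, alpha2 = 0.2,
                           gamma_assoc = 0,
                           sigma2_u = 1, sigma2_v = 0.5, sigma2_eps = 1,
                           psi = 0, omega = 0.20, sigma2_xi = 0.1,
                           gamma_shape = 2.00,
                           censor_lo = 5, censor_hi = 10,
                           regular_interval = 1,
                           treatment_prob = 0.5) {
  dgm <- match.arg(dgm)
  cfg <- list(dgm = dgm,
              n_individuals = as.integer(n_individuals),
              lambda = lambda, p = p, beta = beta,
              alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
              gamma_assoc = gamma_assoc,
              sigma2_u = sigma2_u, sigma2_v = sigma2_v,
              sigma2_eps = sigma2_eps,
              psi = psi, omega = omega, sigma2_xi = sigma2_xi,
              gamma_shape = gamma_shape,
              censor_lo = censor_lo, censor_hi = censor_hi,
              regular_interval = regular_interval,
              treatment_prob = treatment_prob)
  validate_scenario(cfg)
  structure(cfg, class = "visit_scenario")
}

validate_scenario <- function(cfg) {
  with(cfg, {
    stopifnot(n_individuals >= 1L,
              lambda > 0, p > 0, gamma_shape > 0,
              sigma2_u >= 0, sigma2_v >= 0, sigma2_eps >= 0,
              sigma2_xi >= 0,
              censor_lo < censor_hi, censor_lo >= 0,
              regular_interval > 0,
              treatment_prob >= 0, treatment_prob <= 1)
  })
  invisible(cfg)
}

#' @export
print.visit_scenario <- function(x, ...) {
  cat("Visit-process scenario (", x$dgm, ")\n", sep = "")
  cat("  individuals:", x$n_individuals,
      " censoring: U(", x$censor_lo, ",", x$censor_hi, ")\n")
  if (x$dgm %in% c("joint", "joint_regular_visits")) {
    cat("  visit hazard: Weibull(lambda=", x$lambda, ", p=", x$p,
        "), beta=", x$beta, ", gamma=", x$gamma_assoc, "\n", sep = "")
    if (x$dgm == "joint_regular_visits")
      cat("  planned visits every", x$regular_interval, "years\n")
  } else {
    cat("  gaps: Gamma(shape=", x$gamma_shape,
        ", scale=exp(-", x$psi, "*", x$beta, "*Z",
        if (x$dgm == "gamma_lagged_y") paste0(" + ", x$omega, "*y_prev"),
        " + xi)), var(xi)=", x$sigma2_xi, "\n", sep = "")
  }
  cat("  outcome: y = ", x$alpha0, " + ", x$alpha1, "*Z + ",
      x$alpha2, "*t", if (x$dgm %in% c("joint", "joint_regular_visits"))
        paste0(" + ", x$gamma_assoc, "*u"),
      " + v + e;  var(u,v,e) = (", x$sigma2_u, ", ", x$sigma2_v,
      ", ", x$sigma2_eps, ")\n", sep = "")
  invisible(x)
}

#' Read or write a scenario as a flat YAML file
#'
#' Scenario files are flat key-value YAML with the fields of
#' [visit_scenario()]; unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_scenario()` returns a `visit_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(visit_scenario))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  do.call(visit_scenario, cfg)
}

#' @param scenario a `visit_scenario`.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "visit_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' Reference scenario grid
#'
#' The ten study scenarios: Gamma visiting process not depending on
#' treatment, joint-model scenarios crossing gamma in \{0, 1.5\} with
#' lambda in \{0.10, 0.30, 1.00\}, Gamma depending on treatment, Gamma
#' depending on treatment and the previous outcome, and the sparse joint
#' model with yearly planned visits.
#'
#' @return named list of `visit_scenario` objects.
#' @export
scenario_presets <- function() {
  jm <- function(g, l) visit_scenario("joint", gamma_assoc = g, lambda = l)
  list(
    gamma_ind      = visit_scenario("gamma", psi = 0),
    jm_g000_l010   = jm(0.0, 0.10),
    jm_g000_l030   = jm(0.0, 0.30),
    jm_g000_l100   = jm(0.0, 1.00),
    gamma_trt      = visit_scenario("gamma", psi = 2),
    gamma_trt_lagy = visit_scenario("gamma_lagged_y", psi = 2, omega = 0.20),
    jm_g150_l010   = jm(1.5, 0.10),
    jm_g150_l030   = jm(1.5, 0.30),
    jm_g150_l100   = jm(1.5, 1.00),
    jm_g300_l005_regular =
      visit_scenario("joint_regular_visits", gamma_assoc = 3, lambda = 0.05)
  )
}

# True parameter values implied by a scenario, named as estimated.
scenario_truth <- function(cfg) {
  tr <- c(alpha0 = cfg$alpha0, alpha1 = cfg$alpha1, alpha2 = cfg$alpha2,
          sigma2_v = cfg$sigma2_v, sigma2_eps = cfg$sigma2_eps)
  if (cfg$dgm %in% c("joint", "joint_regular_visits"))
    tr <- c(tr, lambda = cfg$lambda, p = cfg$p, beta = cfg$beta,
            gamma = cfg$gamma_assoc, sigma2_u = cfg$sigma2_u)
  tr
}
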