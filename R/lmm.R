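# Linear mixed-model comparators (random intercept, ML not REML):
#   Model D: y = alpha0 + Z alpha1 + t alpha2 + v_i + e
#   Model B: + alpha3 * (n_i centred on the individual-level mean)
#   Model C: + alpha3 * cumulative measurement count (1, 2, 3, ...)

#' Visit-count adjustment covariates
#'
#' Adds the covariate used by the count-adjusted mixed models:
#' `total_count_centred` appends `n_count`, the individual's total
#' number of measurements minus the grand mean over individuals
#' (constant within individual); `cumulative_count` appends the number
#' of measurements recorded up to and including the current one
#' (1, 2, 3, ...); `none` adds nothing.
#'
#' @param data a [visit_panel()].
#' @param adjustment one of `"none"`, `"total_count_centred"`,
#'   `"cumulative_count"`.
#' @return the panel with an `n_count` column on observed rows (`NA` on
#'   censored rows) unless `adjustment = "none"`.
#' @export
build_count_covariates <- function(data,
                                   adjustment = c("none",
                                                  "total_count_centred",
                                                  "cumulative_count")) {
  adjustment <- match.arg(adjustment)
  data <- as_visit_panel(data)
  if (adjustment == "none") return(data)
  obs <- data$d == 1
  n_count <- rep(NA_real_, nrow(data))
  if (adjustment == "total_count_centred") {
    tab <- table(data$id[obs])
    tot <- as.numeric(tab[as.character(data$id[obs])])
    n_count[obs] <- tot - mean(as.numeric(tab))
  } else {
    n_count[obs] <- data$j[obs] + 1
  }
  data$n_count <- n_count
  data
}

# Closed-form ML log-likelihood of the random-intercept model, used for
# the observed information (lme4 reports no variance-component SEs).
lmm_loglik <- function(alpha, s2v, s2e, X, y, id) {
  if (s2e <= 0 || s2v < 0) return(-Inf)
  r <- y - drop(X %*% alpha)
  n <- as.numeric(table(id)[as.character(unique(id))])
  Sr <- rowsum(r, id)[as.character(unique(id)), 1]
  Sr2 <- rowsum(r^2, id)[as.character(unique(id)), 1]
  denom <- s2e + n * s2v
  sum(-0.5 * (n * log(2 * pi) + (n - 1) * log(s2e) + log(denom)) -
        (Sr2 - (s2v / denom) * Sr^2) / (2 * s2e))
}

#' Fit a random-intercept mixed model (Models B, C, D)
#'
#' Maximum-likelihood (not REML) estimation of the Gaussian
#' random-intercept model for the longitudinal outcome, optionally
#' adjusted for a visit-count covariate via
#' [build_count_covariates()]. Point estimation uses `lme4::lmer`;
#' the full covariance of (fixed effects, variance components) is the
#' inverse of the numerically differentiated observed information of
#' the closed-form marginal log-likelihood, so that the variance
#' components carry standard errors on the natural scale.
#'
#' @inheritParams build_count_covariates
#' @return a `visit_lmm_fit` / [`visit_fit`][new_visit_fit] with
#'   estimates `alpha0, alpha1, alpha2, [alpha3,] sigma2_v, sigma2_eps`.
#'   A singular or non-estimable design is reported via
#'   `converged = FALSE` (a count covariate that is identically zero is
#'   dropped, reducing Model B to Model D).
#' @examples
#' sc <- visit_scenario("gamma", n_individuals = 40)
#' fit_lmm(simulate(sc, seed = 3), adjustment = "total_count_centred")
#' @export
fit_lmm <- function(data, adjustment = c("none", "total_count_centred",
                                         "cumulative_count")) {
  adjustment <- match.arg(adjustment)
  method <- switch(adjustment, none = "D", total_count_centred = "B",
                   cumulative_count = "C")
  data <- build_count_covariates(data, adjustment)
  obs <- as.data.frame(data)[data$d == 1, ]
  form <- if (adjustment == "none") y ~ Z + t + (1 | id)
          else y ~ Z + t + n_count + (1 | id)
  has_count <- adjustment != "none"
  if (has_count && all(abs(obs$n_count) < 1e-12)) {
    form <- y ~ Z + t + (1 | id)       # degenerate covariate: drop it
    has_count <- FALSE
  }
  fit <- tryCatch(
    lme4::lmer(form, data = obs, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             lme4::.makeCC("ignore",
                                                           tol = 1e-4))),
    error = function(e) e)
  nm <- c("alpha0", "alpha1", "alpha2", if (has_count) "alpha3",
          "sigma2_v", "sigma2_eps")
  if (inherits(fit, "error")) {
    nav <- stats::setNames(rep(NA_real_, length(nm)), nm)
    return(new_visit_fit(method, nav, nav, converged = FALSE,
                         message = conditionMessage(fit),
                         class = "visit_lmm_fit"))
  }
  fx <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  est <- stats::setNames(c(unname(fx), as.numeric(vc$id),
                           attr(vc, "sc")^2), nm)
  X <- cbind(1, obs$Z, obs$t, if (has_count) obs$n_count)
  k <- length(fx)
  ll_fun <- function(th)
    lmm_loglik(th[seq_len(k)], th[k + 1], th[k + 2], X, obs$y, obs$id)
  H <- tryCatch(pracma::hessian(function(th) -ll_fun(th), unname(est)),
                error = function(e) NULL)
  vcm <- NULL
  se <- rep(NA_real_, length(est))
  conv <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    # non-finite entries arise when a variance sits on the boundary and
    # the finite-difference probe crosses into negative variances
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      vcm <- solve(H)
      dimnames(vcm) <- list(nm, nm)
      se <- sqrt(pmax(diag(vcm), 0))
      conv <- TRUE
    }
  }
  new_visit_fit(method, est, stats::setNames(se, nm), vcov = vcm,
                loglik = as.numeric(stats::logLik(fit)), converged = conv,
                adjustment = adjustment, lmer_fit = fit,
                class = "visit_lmm_fit")
}
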