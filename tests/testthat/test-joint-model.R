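# Joint-model likelihood and ML fit.

# Independent pieces used as oracles ---------------------------------------

# Weibull recurrent-event log-likelihood ignoring the frailty entirely.
weib_loglik_nofrailty <- function(par, data) {
  gp <- data[data$j > 0, ]
  eta <- par["beta"] * gp$Z
  sum(gp$d * (log(par["lambda"] * par["p"]) +
                (par["p"] - 1) * log(gp$gap) + eta) -
        par["lambda"] * gp$gap^par["p"] * exp(eta))
}

# Random-intercept Gaussian log-likelihood by explicit matrix algebra.
lmm_loglik_matrix <- function(par, data) {
  obs <- data[data$d == 1, ]
  ll <- 0
  for (i in unique(obs$id)) {
    oi <- obs[obs$id == i, ]
    r <- oi$y - (par["alpha0"] + par["alpha1"] * oi$Z +
                   par["alpha2"] * oi$t)
    V <- par["sigma2_eps"] * diag(nrow(oi)) +
      par["sigma2_v"] * matrix(1, nrow(oi), nrow(oi))
    ll <- ll - 0.5 * (nrow(oi) * log(2 * pi) +
                        determinant(V)$modulus +
                        drop(t(r) %*% solve(V, r)))
  }
  as.numeric(ll)
}

test_that("severed link factorises the likelihood", {
  dat <- toy_panel()
  par <- ref_params(gamma = 0, sigma2_u = 1e-13)
  expect_equal(joint_loglik(par, dat),
               weib_loglik_nofrailty(par, dat) + lmm_loglik_matrix(par, dat),
               tolerance = 1e-6)
})

test_that("quadrature agrees with brute-force Monte Carlo integration", {
  dat <- toy_panel()
  par <- ref_params()
  ll_quad <- joint_loglik(par, dat, n_quad = 25)
  set.seed(2024)
  M <- 1e6
  u <- rnorm(M, 0, sqrt(par["sigma2_u"]))
  v <- rnorm(M, 0, sqrt(par["sigma2_v"]))
  ll_mc <- 0; var_log <- 0
  for (i in unique(dat$id)) {
    di <- dat[dat$id == i, ]
    gp <- di[di$j > 0, ]
    oi <- di[di$d == 1, ]
    lw <- rep(0, M)
    for (k in seq_len(nrow(gp))) {
      eta <- par["beta"] * gp$Z[k] + u
      lw <- lw + gp$d[k] * (log(par["lambda"] * par["p"]) +
                              (par["p"] - 1) * log(gp$gap[k]) + eta) -
        par["lambda"] * gp$gap[k]^par["p"] * exp(eta)
    }
    for (k in seq_len(nrow(oi))) {
      m <- par["alpha0"] + par["alpha1"] * oi$Z[k] +
        par["alpha2"] * oi$t[k] + par["gamma"] * u + v
      lw <- lw + dnorm(oi$y[k], m, sqrt(par["sigma2_eps"]), log = TRUE)
    }
    w <- exp(lw)
    ll_mc <- ll_mc + log(mean(w))
    var_log <- var_log + var(w) / (M * mean(w)^2)
  }
  expect_lt(abs(ll_quad - ll_mc), 3 * sqrt(var_log))
})

test_that("an outcome-free censored spell integrates only the hazard", {
  par <- ref_params(lambda = 0.4, beta = 0.8, sigma2_u = 0.7)
  one <- data.frame(id = 1, j = 1, t = 2.3, gap = 2.3, d = 0, y = NA,
                    Z = 1, C = 2.3)
  expected <- log(integrate(function(u)
    exp(-par["lambda"] * 2.3^par["p"] * exp(par["beta"] * 1 + u)) *
      dnorm(u, 0, sqrt(par["sigma2_u"])),
    -Inf, Inf, rel.tol = 1e-12)$value)
  expect_equal(joint_loglik(par, one, n_quad = 25, validate = FALSE),
               expected, tolerance = 1e-6)
})

test_that("the likelihood is invariant to row and individual order", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 40), seed = 11)
  par <- ref_params()
  ll <- joint_loglik(par, dat)
  set.seed(1)
  shuffled <- as.data.frame(dat)[sample(nrow(dat)), ]
  expect_equal(joint_loglik(par, shuffled, validate = FALSE), ll,
               tolerance = 1e-10)
})

test_that("adaptive quadrature is converged at moderate node counts", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 100), seed = 21)
  par <- ref_params()
  l15 <- joint_loglik(par, dat, n_quad = 15)
  l25 <- joint_loglik(par, dat, n_quad = 25)
  expect_lt(abs(l15 - l25), 1e-4)
  # the dense non-adaptive fallback agrees where its nodes resolve the
  # posterior (few events per individual)
  toy <- toy_panel()
  expect_lt(abs(joint_loglik(ref_params(), toy, n_quad = 15) -
                  joint_loglik(ref_params(), toy, n_quad = 61,
                               adaptive = FALSE)), 1e-6)
})

test_that("parameter validation rejects invalid inputs", {
  dat <- toy_panel()
  expect_error(joint_loglik(ref_params(lambda = -1), dat), "positive")
  expect_error(joint_loglik(ref_params(sigma2_u = -0.1), dat),
               "non-negative")
  expect_error(joint_loglik(ref_params()[-1], dat), "params")
  expect_error(joint_loglik(ref_params(), dat, n_quad = 2))
})

test_that("time-unit rescaling shifts the likelihood by the Jacobian", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 60), seed = 31)
  cc <- 2.5
  dat2 <- as.data.frame(dat)
  dat2$t <- dat2$t * cc; dat2$gap <- dat2$gap * cc; dat2$C <- dat2$C * cc
  par <- ref_params()
  par2 <- ref_params(lambda = 0.3 * cc^(-1.05), alpha2 = 0.2 / cc)
  n_events <- sum(dat$d[dat$j > 0])
  expect_equal(joint_loglik(par2, dat2), joint_loglik(par, dat) -
                 n_events * log(cc), tolerance = 1e-8)
})

test_that("ML estimates are equivariant under time rescaling", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 100), seed = 41)
  f1 <- fit_joint_model(dat)
  cc <- 2
  dat2 <- as.data.frame(dat)
  dat2$t <- dat2$t * cc; dat2$gap <- dat2$gap * cc; dat2$C <- dat2$C * cc
  f2 <- fit_joint_model(visit_panel(dat2))
  expect_true(f1$converged && f2$converged)
  cf1 <- coef(f1); cf2 <- coef(f2)
  expect_equal(cf2["lambda"], cf1["lambda"] * cc^(-cf1["p"]),
               tolerance = 0.01)
  expect_equal(cf2["alpha2"], cf1["alpha2"] / cc, tolerance = 0.01)
  expect_equal(cf2["p"], cf1["p"], tolerance = 0.01)
  expect_equal(cf2["gamma"], cf1["gamma"], tolerance = 0.02)
})

test_that("the generating parameters sit near the likelihood maximum", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 400), seed = 51)
  par <- ref_params()
  ll0 <- joint_loglik(par, dat)
  for (k in seq_along(par)) {
    pk <- par
    pk[k] <- pk[k] + 0.5
    expect_lt(joint_loglik(pk, dat), ll0)
  }
})

test_that("the ML fit recovers the truth and reports sane uncertainty", {
  dat <- simulate(visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.3,
                                 n_individuals = 300), seed = 61)
  fit <- fit_joint_model(dat)
  expect_true(fit$converged)
  truth <- ref_params()
  expect_true(all(abs(coef(fit) - truth) < 4 * fit$se))
  expect_true(all(fit$se > 0))
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_gt(logLik(fit), joint_loglik(truth, dat))
})

test_that("optimisation failure is flagged, not raised", {
  # two individuals cannot identify a ten-parameter model
  tiny <- toy_panel()[toy_panel()$id != 3, ]
  fit <- fit_joint_model(visit_panel(tiny))
  expect_s3_class(fit, "visit_jm_fit")
  expect_false(isTRUE(fit$converged) &&
                 any(!is.finite(fit$se)))  # flags, no exception
})
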