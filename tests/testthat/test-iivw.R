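# Two-stage IIVW estimator: intensity model, weights, weighted model.

test_that("partial-likelihood estimate matches a brute-force score root", {
  # 2 individuals, 3 observed gaps + censored gaps, hand-enumerable
  dat <- visit_panel(data.frame(
    id  = c(1, 1, 1, 1, 2, 2, 2),
    j   = c(0, 1, 2, 3, 0, 1, 2),
    t   = c(0, 1.0, 2.5, 6.0, 0, 2.0, 5.0),
    gap = c(0, 1.0, 1.5, 3.5, 0, 2.0, 3.0),
    d   = c(1, 1, 1, 0, 1, 1, 0),
    y   = c(0, 1, 2, NA, 0, 1, NA),
    Z   = c(0, 0, 0, 0, 1, 1, 1),
    C   = c(6, 6, 6, 6, 5, 5, 5)))
  fit <- fit_visit_intensity(dat, jackknife = TRUE)
  # Breslow partial log-likelihood over gap-time risk sets, by hand
  gp <- as.data.frame(dat)[dat$j > 0, ]
  pl <- function(eta) {
    lp <- eta * gp$Z
    sum(vapply(which(gp$d == 1), function(k) {
      risk <- gp$gap >= gp$gap[k]
      lp[k] - log(sum(exp(lp[risk])))
    }, numeric(1)))
  }
  root <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(fit$eta), root, tolerance = 1e-6)
  expect_true(all(fit$se_jackknife >= 0))
})

test_that("a covariate unrelated to the gaps has a null coefficient", {
  dat <- simulate(visit_scenario("gamma", psi = 2, n_individuals = 150),
                  seed = 13)
  df <- as.data.frame(dat)
  # permute treatment labels across individuals: breaks the association
  set.seed(14)
  ids <- unique(df$id)
  newZ <- sample(df$Z[!duplicated(df$id)])
  df$Z <- newZ[match(df$id, ids)]
  fit <- fit_visit_intensity(visit_panel(df), jackknife = TRUE)
  expect_lt(abs(fit$eta / fit$se_jackknife), 3)
})

test_that("treatment raises the visit intensity under the Gamma DGM", {
  cfg <- visit_scenario("gamma", psi = 2, n_individuals = 100)
  eta <- vapply(1:50, function(k)
    unname(fit_visit_intensity(simulate(cfg, seed = 400 + k),
                               jackknife = FALSE)$eta), numeric(1))
  expect_true(all(eta > 0))
})

test_that("jackknife SE is in the range of the model-based SE", {
  dat <- simulate(visit_scenario("gamma", psi = 2, n_individuals = 100),
                  seed = 15)
  fit <- fit_visit_intensity(dat, jackknife = TRUE)
  naive <- sqrt(diag(vcov(fit$coxph)))
  expect_true(all(fit$se_jackknife > naive / 3 &
                    fit$se_jackknife < naive * 3))
})

test_that("weight construction follows the centring-and-shift recipe", {
  dat <- toy_panel()
  fit <- fit_visit_intensity(dat, jackknife = FALSE)
  w <- compute_weights(fit, dat)
  expect_equal(mean(w$normalised), 1, tolerance = 1e-12)
  # baseline visits carry weight one
  expect_true(all(w$final[w$j == 0] == 1))
  # visit j inherits the normalised weight of visit j-1 (hand check):
  # raw weights are constant within individual here (time-fixed Z)
  obs <- as.data.frame(dat)[dat$d == 1, ]
  eta <- unname(fit$eta)
  raw <- 1 / exp(eta * obs$Z)
  m <- mean(raw)
  i1 <- which(w$id == 1 & w$j == 1)
  expect_equal(w$final[i1], 1 / exp(eta * 0) - m + 1)
  i2 <- which(w$id == 2 & w$j == 1)
  expect_equal(w$final[i2], 1 / exp(eta * 1) - m + 1)
  # an uninformative intensity model gives unit weights everywhere
  fit0 <- fit
  fit0$eta[] <- 0
  w0 <- compute_weights(fit0, dat)
  expect_true(all(w0$final == 1))
})

test_that("weighted marginal fit equals the closed-form WLS solution", {
  dat <- toy_panel()
  obs <- as.data.frame(dat)[dat$d == 1, ]
  set.seed(16)
  w <- runif(nrow(obs), 0.3, 2)
  fit <- fit_weighted_marginal(dat, w)
  X <- cbind(1, obs$Z, obs$t)
  beta <- drop(solve(t(X) %*% (w * X), t(X) %*% (w * obs$y)))
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-8)
})

test_that("unit weights reduce to pooled OLS with clustered errors", {
  dat <- simulate(visit_scenario("gamma", n_individuals = 50), seed = 17)
  obs <- as.data.frame(dat)[dat$d == 1, ]
  fit <- fit_weighted_marginal(dat, rep(1, nrow(obs)))
  ols <- lm(y ~ Z + t, data = obs)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(sandwich::vcovCL(ols, cluster = obs$id,
                                                 type = "HC0")))),
               tolerance = 1e-10)
})

test_that("point estimates are invariant to rescaling all weights", {
  dat <- simulate(visit_scenario("gamma", psi = 2, n_individuals = 60),
                  seed = 18)
  fit <- fit_iivw(dat, jackknife = FALSE)
  w <- fit$weights$final
  obs_n <- sum(dat$d == 1)
  expect_equal(length(w), obs_n)
  f1 <- fit_weighted_marginal(dat, w)
  f3 <- fit_weighted_marginal(dat, 3 * w)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-10)
})

test_that("misaligned or degenerate weights are rejected", {
  dat <- toy_panel()
  expect_error(fit_weighted_marginal(dat, c(1, 2)), "align")
  obs_n <- sum(dat$d == 1)
  expect_error(fit_weighted_marginal(dat, rep(0, obs_n)), "positive")
  expect_error(fit_weighted_marginal(dat, c(-1, rep(1, obs_n - 1))),
               "negative")
})

test_that("the two-stage wrapper flags stage failures", {
  # no observed gaps beyond baseline: intensity model cannot be fit
  dat <- toy_panel()
  df <- as.data.frame(dat)
  df <- df[df$j == 0 | df$d == 0, ]
  df$j[df$d == 0] <- 1
  df$gap[df$d == 0] <- df$C[df$d == 0]
  df$t[df$d == 0] <- df$C[df$d == 0]
  fit <- fit_iivw(visit_panel(df))
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
})
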