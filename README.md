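# visitjm

Longitudinal data from electronic health records are recorded only when
a patient visits, and visiting is rarely independent of health: sicker
patients are seen more often and contribute more (and worse) biomarker
values. When the *visiting process* is informative in this sense,
ordinary mixed models for the longitudinal outcome can be biased.
`visitjm` is for biostatisticians who need to model such data or to
study estimator behaviour under controlled visiting mechanisms. It
provides:

* **Model A — a joint model** of the visiting and outcome processes,
  linked by a shared random effect. The visit submodel is a Weibull
  recurrent-event model on the gap-time scale,

      r(t̃_ij | Z_i, u_i) = λ p t̃_ij^(p−1) exp(β Z_i + u_i),

  and the outcome submodel is a Gaussian mixed model,

      y_ij = α0 + Z_i α1 + t_ij α2 + γ u_i + v_i + ε_ij,

  with u_i ~ N(0, σ²_u), v_i ~ N(0, σ²_v), ε_ij ~ N(0, σ²_ε). The
  association parameter γ measures how informative the visiting process
  is (γ = 0: not at all). Estimation is by maximum likelihood with the
  random effects integrated out (`fit_joint_model()`; adaptive
  Gauss–Hermite quadrature).
* **Models B, C, D** — random-intercept mixed models adjusting for the
  centred total visit count, the cumulative visit count, or nothing
  (`fit_lmm()`, ML not REML).
* **Model E** — the two-stage inverse-intensity-of-visiting (IIVW)
  estimator: an Andersen–Gill gap-time intensity model with jackknife
  standard errors, centred-and-shifted inverse-intensity weights, and a
  weighted marginal model with cluster-robust variance (`fit_iivw()`).
* **Simulators** for four visiting mechanisms (joint-model visits,
  Gamma gap times depending on treatment and optionally on the previous
  outcome, and a planned regular-visit variant), analytic marginal
  median gap times, and a **Monte Carlo study engine** with bias,
  coverage and MSE plus Monte Carlo standard errors.

## Worked example

Simulate one dataset with a strongly informative visiting process
(γ = 1.5, λ = 0.30) and compare the joint model with the mixed model
that ignores visiting:

```r
library(visitjm)
sc  <- visit_scenario("joint", gamma_assoc = 1.5, lambda = 0.30)
dat <- simulate(sc, seed = 1)
summary(dat)
#> individuals:          200
#> measurements:         1345
#> median per individual: 5
#> median gap (years):   0.489

fit <- fit_joint_model(dat)
summary(fit)
#> Method A
#>            Estimate Std. Error z value Pr(>|z|)
#> lambda      0.34070    0.03947   8.632  < 2e-16 ***
#> p           1.00332    0.02503  40.087  < 2e-16 ***
#> beta        0.79353    0.14533   5.460 4.76e-08 ***
#> alpha0      0.21311    0.17912   1.190  0.23414
#> alpha1      0.69251    0.24368   2.842  0.00449 **
#> alpha2      0.19593    0.01245  15.741  < 2e-16 ***
#> gamma       1.66974    0.12857  12.987  < 2e-16 ***
#> sigma2_u    0.75683    0.11249   6.728 1.72e-11 ***
#> sigma2_v    0.54639    0.12668   4.313 1.61e-05 ***
#> sigma2_eps  1.09742    0.04556  24.086  < 2e-16 ***
#> log-likelihood: -3282.06

coef(fit_lmm(dat, adjustment = "none"))      # Model D
#>     alpha0     alpha1     alpha2   sigma2_v sigma2_eps
#>  0.3017348  0.6530730  0.2061199  2.5293183  1.1028771
```

The generating values were α = (0, 1, 0.2), γ = 1.5, σ²_u = 1,
σ²_v = 0.5, σ²_ε = 1. On this single replicate the joint model detects
the association (γ̂ = 1.67, strongly significant) and keeps σ̂²_v near
its true value, while Model D absorbs the visiting-induced
between-individual variation into an inflated random-intercept variance
(2.53 vs 0.5). Single-replicate coefficient estimates are noisy;
method-level statements (e.g. that Model D systematically underestimates
the treatment effect α1 while Model A does not) come from the study
engine:

```r
res <- run_study(list(jm = sc), methods = c("A", "D"), K = 100,
                 master_seed = 72, jackknife = FALSE)
summarise_study(res)   # bias, coverage, MSE with Monte Carlo SEs
```

Analytic scenario descriptors, e.g. the marginal median gap times
implied by λ = 0.10 with β = 1 and σ²_u = 1:

```r
marginal_median_gap(lambda = 0.10, Z = c(0, 1))
#> [1] 5.826288 2.247906    # years, unexposed vs exposed
```

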