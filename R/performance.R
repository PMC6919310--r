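# Monte Carlo simulation-study engine: replicate x scenario x method
# grid, with performance measures and their Monte Carlo standard errors.

#' Monte Carlo standard errors and replication-count calculus
#'
#' Standard formulas for the uncertainty of simulation-study
#' performance measures over K replications:
#' MCSE(bias) = empSE / sqrt(K); MCSE(coverage) = sqrt(c(1-c)/K);
#' MCSE(empSE) = empSE / sqrt(2(K-1)); MCSE(MSE) = sd(squared
#' errors)/sqrt(K). `replications_required()` inverts the bias formula:
#' the smallest K with MCSE(bias) at or below the target given an
#' anticipated estimator variance.
#'
#' @param emp_se empirical standard error of the estimates.
#' @param K number of replications.
#' @return a numeric scalar.
#' @examples
#' mcse_bias(sqrt(0.1), 1000)          # 0.01
#' mcse_coverage(0.5, 1000)            # 0.0158
#' replications_required(0.1, 0.01)    # 1000
#' @export
mcse_bias <- function(emp_se, K) emp_se / sqrt(K)

#' @param coverage estimated coverage proportion.
#' @rdname mcse_bias
#' @export
mcse_coverage <- function(coverage, K) sqrt(coverage * (1 - coverage) / K)

#' @rdname mcse_bias
#' @export
mcse_emp_se <- function(emp_se, K) emp_se / sqrt(2 * (K - 1))

#' @param sq_errors vector of squared estimation errors.
#' @rdname mcse_bias
#' @export
mcse_mse <- function(sq_errors, K = length(sq_errors))
  stats::sd(sq_errors) / sqrt(K)

#' @param var_hat anticipated variance of the estimator across
#'   replications.
#' @param target_mcse required MCSE for bias.
#' @rdname mcse_bias
#' @export
replications_required <- function(var_hat, target_mcse)
  ceiling(var_hat / target_mcse^2)

# Deterministic per-replicate seed schedule: reproducible per scenario
# and replicate, independent of evaluation order, < 2^31.
replicate_seed <- function(master_seed, scenario_index, replicate) {
  (as.integer(master_seed) %% 100000L) * 20011L +
    scenario_index * 1009L + replicate * 7L
}

#' Run a Monte Carlo simulation study
#'
#' For each scenario and replicate, simulates one dataset (from a
#' deterministic per-replicate seed derived from `master_seed`) and fits
#' every requested method to the same data. Estimation failures are
#' recorded through the `converged` flag, never raised.
#'
#' @param scenarios a named list of [visit_scenario()] objects (a single
#'   scenario is accepted).
#' @param methods character vector of method labels among `"A"` (joint
#'   model), `"B"`, `"C"`, `"D"` (mixed models), `"E"` (IIVW).
#' @param K replications per scenario (>= 2).
#' @param master_seed integer master seed.
#' @param n_quad quadrature nodes for Model A.
#' @param jackknife jackknife SEs in Model E's intensity stage.
#' @return a `visit_study` data frame, one row per (scenario, replicate,
#'   method, estimand): columns `scenario`, `replicate`, `method`,
#'   `estimand`, `estimate`, `se`, `converged`, `truth`.
#' @seealso [summarise_study()]
#' @examples
#' res <- run_study(list(g0 = visit_scenario("gamma", n_individuals = 30)),
#'                  methods = "D", K = 2, master_seed = 1)
#' summarise_study(res)
#' @export
run_study <- function(scenarios, methods = c("A", "B", "C", "D", "E"),
                      K, master_seed = 1L, n_quad = 9L,
                      jackknife = TRUE) {
  if (inherits(scenarios, "visit_scenario"))
    scenarios <- list(scenario = scenarios)
  stopifnot(K >= 2, length(scenarios) >= 1, length(methods) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rows <- list()
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    truth <- scenario_truth(cfg)
    for (r in seq_len(K)) {
      dat <- simulate(cfg, seed = replicate_seed(master_seed, s, r))
      for (m in methods) {
        fit <- fit_method(dat, m, n_quad = n_quad, jackknife = jackknife)
        est <- stats::coef(fit)
        keep <- intersect(names(est), names(truth))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = names(scenarios)[s], replicate = r, method = m,
          estimand = keep, estimate = unname(est[keep]),
          se = unname(fit$se[keep]), converged = fit$converged,
          truth = unname(truth[keep]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("visit_study", "data.frame")
  out
}

#' Summarise a simulation study
#'
#' Per (scenario, method, estimand) cell, over converged replicates:
#' bias (mean and median based), empirical SE, mean model SE, coverage
#' of normal-based 95% confidence intervals, MSE, each with its Monte
#' Carlo standard error, plus the convergence rate.
#'
#' @param results a [run_study()] table.
#' @param truth optional named vector overriding the stored true values.
#' @param level confidence level for coverage (default 0.95).
#' @return a `visit_study_summary` data frame.
#' @export
summarise_study <- function(results, truth = NULL, level = 0.95) {
  stopifnot(all(c("scenario", "method", "estimand", "estimate", "se",
                  "converged") %in% names(results)))
  q <- stats::qnorm(1 - (1 - level) / 2)
  cells <- split(results,
                 list(results$scenario, results$method, results$estimand),
                 drop = TRUE)
  out <- lapply(cells, function(cell) {
    th <- if (!is.null(truth)) truth[cell$estimand[1]]
          else cell$truth[1]
    if (is.null(th) || is.na(th))
      stop("no true value available for estimand '",
           cell$estimand[1], "'")
    K_all <- nrow(cell)
    ok <- cell$converged & is.finite(cell$estimate) & is.finite(cell$se)
    cc <- cell[ok, ]
    K <- nrow(cc)
    if (K < 2) stop("fewer than 2 converged replicates in cell ",
                    cell$scenario[1], "/", cell$method[1], "/",
                    cell$estimand[1])
    err <- cc$estimate - th
    emp <- stats::sd(cc$estimate)
    cov <- mean(abs(err) <= q * cc$se)
    data.frame(
      scenario = cell$scenario[1], method = cell$method[1],
      estimand = cell$estimand[1], truth = th, n_converged = K,
      convergence_rate = K / K_all,
      mean_est = mean(cc$estimate), median_est = stats::median(cc$estimate),
      bias = mean(err), bias_mcse = mcse_bias(emp, K),
      median_bias = stats::median(err),
      empirical_se = emp, empirical_se_mcse = mcse_emp_se(emp, K),
      mean_model_se = mean(cc$se),
      coverage = cov, coverage_mcse = mcse_coverage(cov, K),
      mse = mean(err^2), mse_mcse = mcse_mse(err^2))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("visit_study_summary", "data.frame")
  out
}

#' @export
print.visit_study_summary <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df)
  invisible(x)
}

#' Descriptive statistics of a scenario across simulated datasets
#'
#' Simulates `K` datasets and summarises, per dataset: total number of
#' measurements, median measurements per individual, and median observed
#' gap time. Returns the median of each statistic across datasets with
#' its interquartile interval and the Monte Carlo standard error of the
#' median (1.2533 sd / sqrt(K)).
#'
#' @param scenario a [visit_scenario()].
#' @param K number of simulated datasets.
#' @param master_seed integer master seed.
#' @return data frame with one row per statistic (`n_measurements`,
#'   `median_per_individual`, `median_gap`): columns `median`, `q25`,
#'   `q75`, `mcse_median`.
#' @export
describe_scenario <- function(scenario, K = 1000L, master_seed = 1L) {
  stats <- vapply(seq_len(K), function(r) {
    d <- simulate(scenario,
                  seed = replicate_seed(master_seed, 1L, r))
    obs <- d$d == 1
    c(n_measurements = sum(obs),
      median_per_individual = stats::median(as.numeric(table(d$id[obs]))),
      median_gap = stats::median(d$gap[obs & d$j > 0]))
  }, numeric(3))
  out <- data.frame(
    statistic = rownames(stats),
    median = apply(stats, 1, stats::median),
    q25 = apply(stats, 1, stats::quantile, 0.25),
    q75 = apply(stats, 1, stats::quantile, 0.75),
    mcse_median = 1.2533 * apply(stats, 1, stats::sd) / sqrt(K))
  rownames(out) <- NULL
  out
}
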