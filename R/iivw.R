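# Two-stage inverse-intensity-of-visiting (IIVW) estimator (Model E):
# 1. Andersen-Gill gap-time intensity model r(t~) = r0(t~) exp(z eta),
#    Cox partial likelihood, delete-one-individual jackknife variance;
# 2. visit weights 1/exp(z eta^), centred at one, shifted one visit
#    later within individual (baseline weight 1);
# 3. weighted marginal model E(y) = alpha0 + Z alpha1 + t alpha2 by
#    weighted estimating equations (identity link, independence working
#    correlation) with a cluster-robust sandwich variance.

#' Fit the Andersen-Gill visit-intensity model
#'
#' Cox partial-likelihood fit on the gap-time scale: every gap (rows
#' with visit index j > 0, including each individual's censored terminal
#' gap) is a spell from 0 to the gap length, with the event indicator
#' marking observed visits. Ties use the Breslow approximation. Standard
#' errors are the grouped (delete-one-individual) jackknife.
#'
#' @param data a [visit_panel()].
#' @param covariates character vector of covariate columns (default
#'   `"Z"`).
#' @param jackknife compute leave-one-individual-out jackknife SEs
#'   (refits the model once per individual).
#' @return a `visit_intensity_fit`: list with `eta` (coefficients),
#'   `se_jackknife`, `linpred` (per-gap-row \eqn{e^{z\hat\eta}}),
#'   `converged`, and the underlying `coxph` fit.
#' @export
fit_visit_intensity <- function(data, covariates = "Z",
                                jackknife = TRUE) {
  data <- as_visit_panel(data)
  spells <- as.data.frame(data)[data$j > 0, , drop = FALSE]
  if (sum(spells$d) < 2) stop("need at least 2 observed gaps")
  form <- stats::as.formula(paste("survival::Surv(gap, d) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = spells, ties = "breslow"),
    error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition")) {
    eta <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
    return(structure(list(eta = eta, se_jackknife = eta, linpred = NULL,
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "visit_intensity_fit"))
  }
  eta <- stats::coef(fit)
  se_jk <- rep(NA_real_, length(eta))
  if (jackknife) {
    ids <- unique(spells$id)
    est <- matrix(NA_real_, length(ids), length(eta))
    for (k in seq_along(ids)) {
      fk <- tryCatch(
        survival::coxph(form, data = spells[spells$id != ids[k], ],
                        ties = "breslow", init = eta),
        error = function(e) NULL)
      if (!is.null(fk)) est[k, ] <- stats::coef(fk)
    }
    ok <- stats::complete.cases(est)
    m <- length(ids)
    ctr <- colMeans(est[ok, , drop = FALSE])
    se_jk <- sqrt((m - 1) / m *
                    colSums(sweep(est[ok, , drop = FALSE], 2, ctr)^2))
  }
  Zm <- as.matrix(spells[, covariates, drop = FALSE])
  structure(list(eta = eta,
                 se_jackknife = stats::setNames(se_jk, names(eta)),
                 linpred = exp(drop(Zm %*% eta)),
                 spell_id = spells$id, spell_j = spells$j,
                 covariates = covariates, coxph = fit, converged = TRUE),
            class = "visit_intensity_fit")
}

#' @export
print.visit_intensity_fit <- function(x, digits = 4, ...) {
  cat("Andersen-Gill gap-time visit-intensity model",
      if (!x$converged) " [NOT converged]", "\n", sep = "")
  print(round(rbind(eta = x$eta, `jackknife SE` = x$se_jackknife), digits))
  invisible(x)
}

#' Inverse-intensity visit weights
#'
#' Builds the analysis weights from a fitted intensity model: the raw
#' weight of each observed visit is \eqn{1/e^{z\hat\eta}}; raw weights
#' are normalised by subtracting their mean and adding one (so they
#' average exactly one); each individual's weights are then shifted one
#' visit later — the analysis weight of visit j is the normalised
#' weight of visit j-1, the baseline visit receives weight one, and the
#' last visit's normalised weight (corresponding to the end of
#' follow-up) is discarded. Censored terminal rows carry no weight.
#'
#' @param fit a converged [fit_visit_intensity()] result.
#' @param data the same [visit_panel()].
#' @return a `visit_weights` data frame (`id`, `j`, `raw`, `normalised`,
#'   `final`), one row per observed visit; the number of discarded
#'   end-of-follow-up weights is in attribute `"n_discarded"`.
#' @export
compute_weights <- function(fit, data) {
  stopifnot(inherits(fit, "visit_intensity_fit"), fit$converged)
  data <- as_visit_panel(data)
  obs <- as.data.frame(data)[data$d == 1, , drop = FALSE]
  Zm <- as.matrix(obs[, fit$covariates, drop = FALSE])
  raw <- 1 / exp(drop(Zm %*% fit$eta))
  normalised <- raw - mean(raw) + 1
  final <- rep(NA_real_, nrow(obs))
  for (idx in split(seq_len(nrow(obs)), obs$id)) {
    o <- idx[order(obs$j[idx])]
    final[o[1]] <- 1
    if (length(o) > 1)
      final[o[-1]] <- normalised[o[-length(o)]]
  }
  structure(data.frame(id = obs$id, j = obs$j, raw = raw,
                       normalised = normalised, final = final),
            n_discarded = length(unique(obs$id)),
            class = c("visit_weights", "data.frame"))
}

#' Weighted marginal model for the longitudinal outcome
#'
#' Fits E(y) = alpha0 + Z alpha1 + t alpha2 by weighted estimating
#' equations with identity link and independence working correlation
#' (weighted least squares), using the IIVW analysis weights as
#' probability weights, with a cluster-robust sandwich variance
#' clustered on individual.
#'
#' @param data a [visit_panel()].
#' @param weights a [compute_weights()] table aligned to the panel's
#'   observed rows (or a numeric vector, one weight per observed row).
#' @return a `visit_iivw_fit` / [`visit_fit`][new_visit_fit] with
#'   estimates `alpha0, alpha1, alpha2`.
#' @export
fit_weighted_marginal <- function(data, weights) {
  data <- as_visit_panel(data)
  obs <- as.data.frame(data)[data$d == 1, , drop = FALSE]
  w <- if (inherits(weights, "visit_weights")) {
    key <- paste(obs$id, obs$j)
    weights$final[match(key, paste(weights$id, weights$j))]
  } else as.numeric(weights)
  if (length(w) != nrow(obs) || anyNA(w))
    stop("weights do not align with the observed rows")
  if (sum(w) <= 0) stop("total weight must be positive")
  if (any(w < 0))
    stop("negative analysis weights: intensity model too extreme")
  fit <- stats::lm(y ~ Z + t, data = obs, weights = w)
  vc <- sandwich::vcovCL(fit, cluster = obs$id, type = "HC0")
  nm <- c("alpha0", "alpha1", "alpha2")
  est <- stats::setNames(unname(stats::coef(fit)), nm)
  dimnames(vc) <- list(nm, nm)
  new_visit_fit("E", est, sqrt(diag(vc)), vcov = vc,
                converged = TRUE, lm_fit = fit,
                class = "visit_iivw_fit")
}

#' Two-stage IIVW estimator (Model E)
#'
#' Convenience wrapper chaining [fit_visit_intensity()],
#' [compute_weights()] and [fit_weighted_marginal()].
#'
#' @inheritParams fit_visit_intensity
#' @return a `visit_iivw_fit` carrying the stage-one fit (`intensity`)
#'   and the weight table (`weights`). A failed intensity fit is
#'   reported via `converged = FALSE`.
#' @examples
#' sc <- visit_scenario("gamma", psi = 2, n_individuals = 60)
#' fit_iivw(simulate(sc, seed = 11), jackknife = FALSE)
#' @export
fit_iivw <- function(data, covariates = "Z", jackknife = TRUE) {
  data <- as_visit_panel(data)
  stage1 <- tryCatch(
    fit_visit_intensity(data, covariates, jackknife = jackknife),
    error = function(e) e)
  nm <- c("alpha0", "alpha1", "alpha2")
  if (inherits(stage1, "error") || !stage1$converged) {
    nav <- stats::setNames(rep(NA_real_, 3), nm)
    msg <- if (inherits(stage1, "error")) conditionMessage(stage1)
           else stage1$message
    return(new_visit_fit("E", nav, nav, converged = FALSE, message = msg,
                         class = "visit_iivw_fit"))
  }
  w <- compute_weights(stage1, data)
  out <- tryCatch(fit_weighted_marginal(data, w), error = function(e) e)
  if (inherits(out, "error")) {
    nav <- stats::setNames(rep(NA_real_, 3), nm)
    return(new_visit_fit("E", nav, nav, converged = FALSE,
                         message = conditionMessage(out),
                         class = "visit_iivw_fit"))
  }
  out$intensity <- stage1
  out$weights <- w
  out
}
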