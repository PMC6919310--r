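#' Fitted-model container
#'
#' All estimators in the package return a `visit_fit`: a list with the
#' method label, named coefficient vector, standard errors, covariance
#' matrix of the estimates, maximised log-likelihood (where defined),
#' and a convergence flag. Subclasses add estimator-specific components
#' (e.g. quadrature settings for the joint model, the weight table for
#' the weighted marginal model).
#'
#' @param method short method label (e.g. `"A"`, `"lmm"`, `"iivw"`).
#' @param coefficients named numeric vector of estimates.
#' @param se named numeric vector of standard errors.
#' @param vcov covariance matrix of the estimates (may be `NULL`).
#' @param loglik maximised log-likelihood or `NA`.
#' @param converged logical convergence flag.
#' @param ... extra components stored on the object.
#' @param class extra S3 classes to prepend.
#' @return an object of class `visit_fit`.
#' @keywords internal
new_visit_fit <- function(method, coefficients, se, vcov = NULL,
                          loglik = NA_real_, converged = TRUE, ...,
                          class = character()) {
  stopifnot(length(coefficients) == length(se))
  se <- stats::setNames(se, names(coefficients))
  structure(list(method = method, coefficients = coefficients, se = se,
                 vcov = vcov, loglik = loglik, converged = converged, ...),
            class = c(class, "visit_fit"))
}

#' @export
coef.visit_fit <- function(object, ...) object$coefficients

#' @export
vcov.visit_fit <- function(object, ...) object$vcov

#' @export
logLik.visit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.visit_fit <- function(x, digits = 4, ...) {
  cat("Method ", x$method, if (!x$converged) "  [NOT converged]", "\n",
      sep = "")
  print(round(x$coefficients, digits))
  if (is.finite(x$loglik))
    cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  invisible(x)
}

#' @export
summary.visit_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(method = object$method, table = tab,
              loglik = object$loglik, converged = object$converged)
  class(out) <- "summary.visit_fit"
  out
}

#' @export
print.summary.visit_fit <- function(x, digits = 4, ...) {
  cat("Method ", x$method, if (!x$converged) "  [NOT converged]", "\n",
      sep = "")
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (is.finite(x$loglik))
    cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  invisible(x)
}

#' @export
confint.visit_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - q * object$se[parm],
               cf[parm] + q * object$se[parm])
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  out
}

# Fixed-effect linear predictor alpha0 + Z alpha1 + t alpha2 shared by
# every estimator's longitudinal mean model.
#' @export
predict.visit_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  cf["alpha0"] + newdata$Z * cf["alpha1"] + newdata$t * cf["alpha2"]
}

#' @export
residuals.visit_fit <- function(object, data, ...) {
  data <- as_visit_panel(data)
  obs <- data[data$d == 1, ]
  obs$y - predict(object, obs)
}

#' Write a fitted model as JSON
#'
#' Serialises estimates, standard errors, covariance matrix,
#' log-likelihood, and convergence state.
#'
#' @param fit a `visit_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "visit_fit"))
  out <- list(method = fit$method,
              estimates = as.list(fit$coefficients),
              se = as.list(fit$se),
              vcov = fit$vcov,
              loglik = fit$loglik,
              converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
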