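#' Fit one of the competing estimators by label
#'
#' Dispatches to the five estimators compared in the package:
#' `"A"` the joint model ([fit_joint_model()]); `"B"` the mixed model
#' adjusting for the centred total visit count; `"C"` the mixed model
#' adjusting for the cumulative visit count; `"D"` the plain mixed
#' model ([fit_lmm()]); `"E"` the IIVW weighted marginal model
#' ([fit_iivw()]).
#'
#' @param data a [visit_panel()].
#' @param method one of `"A"`..`"E"`.
#' @param n_quad quadrature nodes (Model A only).
#' @param jackknife jackknife SEs in the intensity stage (Model E only).
#' @return a [`visit_fit`][new_visit_fit].
#' @export
fit_method <- function(data, method = c("A", "B", "C", "D", "E"),
                       n_quad = 9L, jackknife = TRUE) {
  method <- match.arg(method)
  switch(method,
         A = fit_joint_model(data, n_quad = n_quad),
         B = fit_lmm(data, adjustment = "total_count_centred"),
         C = fit_lmm(data, adjustment = "cumulative_count"),
         D = fit_lmm(data, adjustment = "none"),
         E = fit_iivw(data, jackknife = jackknife))
}
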