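#' Long-format visit panel data
#'
#' A `visit_panel` is a data frame with one row per recorded measurement
#' plus one censored terminal gap per individual:
#'
#' * `id` — individual identifier;
#' * `j` — visit index (0 = baseline);
#' * `t` — observation time in years from baseline;
#' * `gap` — gap time since the previous observation (0 at baseline);
#' * `d` — event indicator: 1 = observed visit, 0 = censored terminal gap;
#' * `y` — longitudinal outcome (`NA` on censored rows);
#' * `Z` — binary treatment;
#' * `C` — administrative censoring time.
#'
#' Simulated panels carry the per-individual latent draws (`u`, `v`,
#' `xi`) in the `"latents"` attribute; they are never used by the
#' estimators.
#'
#' @param data a data frame with the columns above.
#' @param latents optional data frame of per-individual latent values.
#' @return `visit_panel()` / `as_visit_panel()` return a validated
#'   `visit_panel`.
#' @export
visit_panel <- function(data, latents = NULL) {
  cols <- c("id", "j", "t", "gap", "d", "y", "Z", "C")
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing panel columns: ", paste(miss, collapse = ", "))
  out <- as.data.frame(data)[, cols]
  if (!is.null(latents)) attr(out, "latents") <- as.data.frame(latents)
  class(out) <- c("visit_panel", "data.frame")
  validate_panel(out)
  out
}

#' @rdname visit_panel
#' @export
as_visit_panel <- function(data) {
  if (inherits(data, "visit_panel")) return(data)
  visit_panel(data, latents = attr(data, "latents"))
}

#' Check the structural invariants of a visit panel
#'
#' Verifies, per individual: exactly one baseline row (`j = 0`, `t = 0`,
#' `d = 1`); strictly increasing observation times; a final censored row
#' with `gap = C - t_last`; observed gaps plus the censored gap summing
#' to `C`; outcomes present exactly on observed rows; binary treatment.
#'
#' @param data a `visit_panel` (or coercible data frame).
#' @param tol numeric tolerance for the gap-accounting identities.
#' @return the data, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_panel <- function(data, tol = 1e-8) {
  stopifnot(all(data$Z %in% c(0, 1)))
  if (any(data$d == 1 & is.na(data$y)) || any(data$d == 0 & !is.na(data$y)))
    stop("outcome must be present exactly on observed (d = 1) rows")
  # work on rows ordered by individual (first appearance) then visit index
  uid <- match(data$id, unique(data$id))
  o <- order(uid, data$j)
  uid <- uid[o]
  j <- data$j[o]; t <- data$t[o]; gap <- data$gap[o]; d <- data$d[o]
  Z <- data$Z[o]; C <- data$C[o]
  n <- length(uid)
  first <- c(TRUE, uid[-1] != uid[-n])
  last <- c(first[-1], TRUE)
  if (any(j[first] != 0) || any(t[first] != 0) || any(d[first] != 1) ||
      sum(j == 0) != sum(first))
    stop("each individual needs exactly one baseline row (j=0, t=0, d=1)")
  within <- !first
  if (any((t[-1] - t[-n])[within[-1]] <= 0))
    stop("observation times must be strictly increasing within individual")
  if (any(d[last] != 0))
    stop("final row of each individual must be the censored gap (d = 0)")
  if (any(d[!last] != 1))
    stop("only the final row of an individual may have d = 0")
  if (any(first & last))
    stop("each individual needs a baseline row and a censored gap row")
  wl <- which(last)
  if (any(abs(gap[wl] - (C[wl] - t[wl - 1L])) > tol))
    stop("censored gap must equal C minus the last observed time")
  if (any(abs(rowsum(gap, uid) - C[first]) > tol))
    stop("gaps (observed + censored) must sum to the censoring time C")
  ev <- within & d == 1
  if (any(abs((t - c(0, t[-n]))[ev] - gap[ev]) > tol))
    stop("observed gaps must equal successive time differences")
  if (any((Z[-1] != Z[-n] | C[-1] != C[-n])[within[-1]]))
    stop("Z and C must be constant within individual")
  invisible(data)
}

#' @export
print.visit_panel <- function(x, ...) {
  nid <- length(unique(x$id))
  nobs <- sum(x$d == 1)
  cat("Visit panel: ", nid, " individuals, ", nobs, " measurements (",
      nrow(x), " rows incl. censored gaps)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more rows\n", sep = "")
  invisible(x)
}

#' Per-panel descriptive statistics
#'
#' @param object a `visit_panel`.
#' @param ... unused.
#' @return list with the number of measurements (observed rows), median
#'   measurements per individual, and median observed gap time (baseline
#'   rows excluded).
#' @export
summary.visit_panel <- function(object, ...) {
  obs <- object[object$d == 1, ]
  out <- list(
    n_individuals = length(unique(object$id)),
    n_measurements = nrow(obs),
    median_measurements = stats::median(as.numeric(table(obs$id))),
    median_gap = stats::median(obs$gap[obs$j > 0])
  )
  class(out) <- "summary.visit_panel"
  out
}

#' @export
print.summary.visit_panel <- function(x, ...) {
  cat("individuals:         ", x$n_individuals, "\n")
  cat("measurements:        ", x$n_measurements, "\n")
  cat("median per individual:", x$median_measurements, "\n")
  cat("median gap (years):  ", format(x$median_gap, digits = 3), "\n")
  invisible(x)
}

#' Read and write visit panels as CSV
#'
#' Column order `id, j, t, gap, d, y, Z, C`; a missing outcome (censored
#' terminal rows) is written as an empty field.
#'
#' @param data a `visit_panel`.
#' @param path file path.
#' @return `read_panel()` returns a `visit_panel`; `write_panel()`
#'   returns `path` invisibly.
#' @export
write_panel <- function(data, path) {
  data <- as_visit_panel(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  visit_panel(df)
}
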