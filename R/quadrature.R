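# Gauss-Hermite rules (physicists' weight exp(-x^2)) via Golub-Welsch.
# Cached per node count; node counts in this package are small (<= 101).
gauss_hermite <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n == 1L) {
      rule <- list(nodes = 0, weights = sqrt(pi))
    } else {
      i <- seq_len(n - 1L)
      b <- sqrt(i / 2)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1L)] <- b
      J[cbind(i + 1L, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      ord <- order(e$values)
      rule <- list(nodes   = e$values[ord],
                   weights = sqrt(pi) * e$vectors[1L, ord]^2)
    }
    cache[[key]] <- rule
    rule
  }
})

# Expectation of f(u) for u ~ N(0, sigma2) by n-node Gauss-Hermite.
# f must be vectorised over u.
gh_expect <- function(f, sigma2, n = 41L) {
  if (sigma2 == 0) return(f(0))
  rule <- gauss_hermite(n)
  u <- sqrt(2 * sigma2) * rule$nodes
  w <- rule$weights / sqrt(pi)
  sum(w * f(u))
}
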