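# Shared fixtures: small panels built in code.

# Deterministic toy panel: explicit rows, no simulation.
toy_panel <- function() {
  visit_panel(data.frame(
    id  = c(1, 1, 1, 1, 2, 2, 2, 3, 3),
    j   = c(0, 1, 2, 3, 0, 1, 2, 0, 1),
    t   = c(0, 1.2, 2.0, 6.0, 0, 0.5, 5.5, 0, 7.0),
    gap = c(0, 1.2, 0.8, 4.0, 0, 0.5, 5.0, 0, 7.0),
    d   = c(1, 1, 1, 0, 1, 1, 0, 1, 0),
    y   = c(0.2, 1.1, 0.8, NA, -0.4, 0.3, NA, 1.9, NA),
    Z   = c(0, 0, 0, 0, 1, 1, 1, 1, 1),
    C   = c(6, 6, 6, 6, 5.5, 5.5, 5.5, 7, 7)))
}

# Balanced panel: every individual observed at the same times.
balanced_panel <- function(n = 12, times = c(0, 1, 2, 3), seed = 42) {
  set.seed(seed)
  Z <- rep(0:1, length.out = n)
  v <- rnorm(n, 0, sqrt(0.5))
  C <- max(times) + 1
  rows <- lapply(seq_len(n), function(i) {
    y <- 0.5 + Z[i] + 0.2 * times + v[i] + rnorm(length(times))
    data.frame(id = i, j = c(seq_along(times) - 1, length(times)),
               t = c(times, C),
               gap = c(0, diff(times), C - max(times)),
               d = c(rep(1, length(times)), 0),
               y = c(y, NA), Z = Z[i], C = C)
  })
  visit_panel(do.call(rbind, rows))
}

ref_params <- function(...) {
  par <- c(lambda = 0.3, p = 1.05, beta = 1, alpha0 = 0, alpha1 = 1,
           alpha2 = 0.2, gamma = 1.5, sigma2_u = 1, sigma2_v = 0.5,
           sigma2_eps = 1)
  over <- c(...)
  par[names(over)] <- over
  par
}
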