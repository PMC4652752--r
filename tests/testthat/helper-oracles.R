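# Independent oracles and shared fixtures, built in code at test time.

# Naive O(n^2) periodic LOESS: for every bin, select the q nearest usable
# points by circular distance (ties included; boundary points carry zero
# tricube weight), fit a weighted quadratic in signed local coordinates
# with stats::solve, evaluate at the centre. Deliberately independent of
# the package's windowed implementation.
naive_periodic_loess <- function(y, use, q) {
  n <- length(y)
  out <- numeric(n)
  pts <- which(use) - 1L
  for (i in 0:(n - 1L)) {
    d <- abs(pts - i)
    d <- pmin(d, n - d)
    dmax <- sort(d, partial = q)[q]
    sel <- d <= dmax
    u <- ((pts[sel] - i + n %/% 2L) %% n) - n %/% 2L
    w <- ifelse(abs(u) < dmax, (1 - (abs(u) / dmax)^3)^3, 0)
    X <- cbind(1, u, u^2)
    out[i + 1L] <- solve(crossprod(X, w * X), crossprod(X, w * y[pts[sel] + 1L]))[1L]
  }
  out
}

# Non-periodic reference: stats::loess on the profile tiled three times,
# evaluated on the middle copy. Valid when frac * 3 <= 1 and frac * n is
# an integer (so both implementations select the same neighbourhoods).
tiled_loess_oracle <- function(y, frac) {
  n <- length(y)
  y3 <- rep(y, 3L)
  x3 <- 0:(3L * n - 1L)
  fit <- stats::loess(y3 ~ x3, span = frac / 3, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  stats::predict(fit)[(n + 1L):(2L * n)]
}

# small circular chromosome for kinetic unit tests (bins of 1 kb)
toy_config <- function(L = 10000, origins = c(ori = 0), ...) {
  chrom_config(L, origins, ...)
}

# noise-free enrichment track for a model configuration
noise_free_profile <- function(config, doubling_time_min) {
  tm <- simulate_replication_timing(
    config, simulation_params(doubling_time_min = doubling_time_min))
  cn <- timing_to_copy_number(tm, doubling_time_min)
  list(timing = tm, profile = mfa_profile(cn / mean(cn)))
}
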