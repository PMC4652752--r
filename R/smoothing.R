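#' Smoothing parameters for the periodic LOESS
#'
#' @param frac Fraction of the data used for each local fit (span). The
#'   default 0.10 on a 1-kb-binned 4.64 Mbp genome corresponds to a
#'   smoothing window of around 460 kbp.
#' @param degree Local polynomial degree; fixed at 2.
#' @param outlier_threshold Squared-residual cutoff: data points with
#'   `(enrichment - fitted)^2` above it are removed before refitting.
#' @param refit_passes Number of remove-and-refit passes performed by
#'   [remove_outliers_and_refit()].
#' @return A list of class `smoothing_params`.
#' @export
smoothing_params <- function(frac = 0.10, degree = 2,
                             outlier_threshold = 0.02, refit_passes = 1) {
  stopifnot(frac > 0, frac <= 1, outlier_threshold > 0, refit_passes >= 1)
  if (degree != 2) stop("only degree-2 local fits are supported")
  structure(list(frac = frac, degree = 2L,
                 outlier_threshold = outlier_threshold,
                 refit_passes = as.integer(refit_passes)),
            class = "smoothing_params")
}

#' Tricube kernel weight
#'
#' `w = (1 - (d/d_max)^3)^3` for `d < d_max`, else 0.
#'
#' @param d Nonnegative distance(s).
#' @param d_max Window radius (> 0).
#' @export
tricube_weight <- function(d, d_max) {
  if (d_max <= 0) stop("d_max must be positive")
  if (any(d < 0)) stop("distances must be nonnegative")
  ifelse(d < d_max, (1 - (d / d_max)^3)^3, 0)
}

# Core periodic LOESS: y = values on a regular circular grid of n bins,
# use = logical, points contributing to fits; every bin is evaluated.
# q nearest points by circular distance, tricube weights with d_max the
# distance of the furthest selected point (boundary ties get weight 0, so
# including or excluding them leaves the fit unchanged).
.loess_circular <- function(y, use, q) {
  n <- length(y)
  m <- sum(use)
  if (q < 3L) stop("cannot fit a local quadratic with fewer than 3 points")
  if (q > m) stop("span larger than the number of usable points")

  if (m == n) {
    # regular unmasked grid: one symmetric kernel, applied by circular shifts
    H <- if (q %% 2L) (q - 1L) %/% 2L else q %/% 2L
    offs <- (-H):H
    wts <- tricube_weight(abs(offs), H)
    X <- cbind(1, offs, offs^2)
    kern <- drop(solve(crossprod(X, wts * X), t(wts * X))[1L, ])
    fitted <- numeric(n)
    i0 <- 0:(n - 1L)
    for (j in seq_along(offs))
      fitted <- fitted + kern[j] * y[((i0 + offs[j]) %% n) + 1L]
    return(fitted)
  }

  pts <- which(use) - 1L                  # 0-based positions, sorted
  cd <- function(a, b) { d <- abs(a - b); pmin(d, n - d) }
  cost <- function(s, i)                  # max distance over window start s
    max(cd(pts[s + 1L], i), cd(pts[((s + q - 1L) %% m) + 1L], i))
  # two-pointer sweep: the q-nearest window start is monotone in the target
  s <- which.min(vapply(0:(m - 1L), cost, 0, i = 0L)) - 1L
  s_vec <- integer(n)
  guard <- 0L
  for (i in 0:(n - 1L)) {
    while (cost((s + 1L) %% m, i) < cost(s, i)) {
      s <- (s + 1L) %% m
      guard <- guard + 1L
      if (guard > 2L * (n + m)) stop("internal error: window search diverged")
    }
    s_vec[i + 1L] <- s
  }
  # vectorized weighted quadratic in normalized local coordinates u/dmax
  P <- matrix(pts[(outer(s_vec, 0:(q - 1L), "+") %% m) + 1L], n, q)
  U <- ((P - (0:(n - 1L)) + n %/% 2L) %% n) - n %/% 2L
  D <- abs(U)
  dmax <- D[cbind(seq_len(n), max.col(D, ties.method = "first"))]
  dmax[dmax == 0] <- 1
  U <- U / dmax
  W <- (1 - abs(U)^3)^3
  Y <- matrix(y[P + 1L], n, q)
  S0 <- rowSums(W);       S1 <- rowSums(W * U)
  WU2 <- W * U^2
  S2 <- rowSums(WU2);     S3 <- rowSums(WU2 * U); S4 <- rowSums(WU2 * U^2)
  T0 <- rowSums(W * Y);   T1 <- rowSums(W * U * Y); T2 <- rowSums(WU2 * Y)
  det <- S0 * (S2 * S4 - S3^2) - S1 * (S1 * S4 - S3 * S2) +
    S2 * (S1 * S3 - S2^2)
  num <- T0 * (S2 * S4 - S3^2) - S1 * (T1 * S4 - S3 * T2) +
    S2 * (T1 * S3 - T2 * S2)
  # fall back to the weighted mean where the local system degenerates
  ifelse(abs(det) > 1e-10 * pmax(S0, 1)^3, num / det, T0 / S0)
}

#' Periodic LOESS smoothing of a marker-frequency profile
#'
#' Locally weighted quadratic regression on the circular genome: for each
#' bin the `q = round(frac * n_points)` nearest unmasked points by
#' circular distance are fitted with tricube weights in local coordinates
#' re-centred at the bin, so the fit is continuous through the coordinate
#' wrap (periodic boundary conditions). Masked bins receive fitted values
#' by evaluation but never contribute to fits.
#'
#' @param y An [mfa_profile()] (or a plain numeric vector, taken as an
#'   unmasked per-bin track).
#' @param params A [smoothing_params()].
#' @param bin_width Bin width in bp (used only when `y` is numeric).
#' @return An object of class `smoothed_profile`: `fitted` (per-bin),
#'   `retained` (points that contributed), `mask`, `q`, `window_bp`, and
#'   the parameters used.
#' @export
loess_periodic <- function(y, params = smoothing_params(), bin_width = 1000) {
  if (inherits(y, "mfa_profile")) {
    vals <- y$enrichment; mask <- y$mask
    bin_width <- y$bin_width; L <- y$genome_length
  } else {
    vals <- as.numeric(y); mask <- !is.finite(vals)
    L <- length(vals) * bin_width
  }
  stopifnot(inherits(params, "smoothing_params"))
  use <- !mask
  if (!any(use)) stop("all bins are masked")
  q <- as.integer(round(params$frac * sum(use)))
  v <- vals; v[mask] <- 0   # never read where use is FALSE
  fitted <- .loess_circular(v, use, q)
  structure(list(fitted = fitted, retained = use, mask = mask,
                 q = q, window_bp = q * bin_width, bin_width = bin_width,
                 genome_length = L, n_points_used = sum(use),
                 params = params),
            class = "smoothed_profile")
}

#' Remove outliers against the LOESS curve and refit
#'
#' The local regression is sensitive to outliers, so data points whose
#' squared deviation from the fitted curve exceeds
#' `params$outlier_threshold` — `(measured enrichment - LOESS value)^2 >
#' 0.02` by default — are removed and the curve is refitted on the
#' retained points. Removed points are still evaluated (they keep fitted
#' values); they are only excluded from fitting. One removal pass is the
#' default; the procedure is idempotent once no residual exceeds the
#' threshold.
#'
#' @inheritParams loess_periodic
#' @return A `smoothed_profile` whose `retained` flags the surviving
#'   points.
#' @export
remove_outliers_and_refit <- function(y, params = smoothing_params(),
                                      bin_width = 1000) {
  s <- loess_periodic(y, params, bin_width)
  vals <- if (inherits(y, "mfa_profile")) y$enrichment else as.numeric(y)
  unmasked <- !s$mask
  retained <- unmasked
  for (pass in seq_len(params$refit_passes)) {
    resid2 <- (vals - s$fitted)^2
    new_ret <- unmasked & !is.na(resid2) & resid2 <= params$outlier_threshold
    if (identical(new_ret, retained) && pass > 1L) break
    if (identical(new_ret, retained) && all(retained == unmasked)) break
    retained <- new_ret
    q <- as.integer(round(params$frac * sum(retained)))
    v <- vals; v[!retained] <- 0
    s$fitted <- .loess_circular(v, retained, q)
    s$q <- q; s$window_bp <- q * s$bin_width
    s$n_points_used <- sum(retained)
  }
  s$retained <- retained
  s
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf(
    "<smoothed_profile> %d bins; span %.0f%% (q = %d points, window ~%d kbp)\n",
    length(x$fitted), 100 * x$params$frac, x$q, smoothing_window_kbp(x)))
  cat(sprintf("  points retained: %d of %d unmasked\n",
              sum(x$retained), sum(!x$mask)))
  invisible(x)
}

#' Smoothing window implied by the span, in kbp
#'
#' The window spanned by the `q` points of each local fit, `q * bin_width`,
#' reported rounded to the nearest 10 kbp (so the default 10% span on the
#' 1-kb-binned 4.64 Mbp model genome reports 460 kbp).
#'
#' @param x A `smoothed_profile`, or the number of fitted points `n` (in
#'   which case `frac` and `bin_width` are used).
#' @param frac,bin_width Span and bin width when `x` is a count.
#' @return Window size in kbp, rounded to the nearest 10.
#' @export
smoothing_window_kbp <- function(x, frac = 0.10, bin_width = 1000) {
  wbp <- if (inherits(x, "smoothed_profile")) x$window_bp
         else round(frac * x) * bin_width
  round(wbp / 1000 / 10) * 10
}
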