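#' Estimate a doubling time from a viable-count growth curve
#'
#' Ordinary least squares of `log2(cfu)` against time over a selected
#' window; the doubling time is the reciprocal of the slope. The default
#' window, 60-180 min after dilution into fresh broth, is where batch
#' cultures are reliably exponential. The estimate is exactly invariant
#' to the cfu unit scale. A nonpositive slope (no growth) and zero counts
#' inside the window are errors, not silent drops.
#'
#' @param curve A [simulate_growth_curve()] result, or a `data.frame`/list
#'   with `times_min` and `cfu_per_ml`.
#' @param window Numeric length-2: window start and end in minutes.
#' @return Object of class `doubling_time_fit`: `doubling_time_min`,
#'   `r_squared`, `n_points`, `window_used`, and the underlying `lm` fit.
#' @examples
#' gc <- simulate_growth_curve(data.frame(fraction = 1, doubling_time_min = 20))
#' fit_doubling_time(gc)$doubling_time_min  # 20
#' @export
fit_doubling_time <- function(curve, window = c(60, 180)) {
  t <- curve$times_min
  cfu <- curve$cfu_per_ml
  stopifnot(length(t) == length(cfu), length(window) == 2L,
            window[1] < window[2])
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3L) stop("need at least 3 points inside the window")
  if (any(cfu[sel] <= 0))
    stop("nonpositive counts inside the window: log-linear fit undefined")
  fit <- stats::lm(y ~ t, data = data.frame(t = t[sel], y = log2(cfu[sel])))
  slope <- stats::coef(fit)[["t"]]
  if (slope <= 0) stop("nonpositive growth slope: no doubling time estimate")
  y <- log2(cfu[sel])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(doubling_time_min = 1 / slope,
                 r_squared = r2,
                 n_points = sum(sel),
                 window_used = c(start_min = max(window[1], min(t[sel])),
                                 end_min = min(window[2], max(t[sel]))),
                 lm_fit = fit),
            class = "doubling_time_fit")
}

#' @export
print.doubling_time_fit <- function(x, ...) {
  cat(sprintf(
    "<doubling_time_fit> %.1f min (r^2 = %.4f, %d points, %g-%g min)\n",
    x$doubling_time_min, x$r_squared, x$n_points,
    x$window_used[1], x$window_used[2]))
  invisible(x)
}
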