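#' Roughness of a circular per-bin track
#'
#' Mean squared difference between adjacent bins around the circle,
#' computed over pairs where both bins are unmasked. A replication
#' profile that is continuous everywhere is smooth at bin scale; mapping
#' reads from a rearranged chromosome onto the reference arrangement
#' introduces discontinuities that inflate this objective.
#'
#' @param x Numeric per-bin values (`NA` = masked), at least 3 bins.
#' @return Nonnegative mean squared adjacent difference.
#' @examples
#' roughness(c(0, 1, 0, 1))  # 1
#' @export
roughness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 bins")
  a <- x; b <- x[c(2:n, 1L)]
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) stop("all adjacent pairs are masked")
  mean((b[ok] - a[ok])^2)
}

#' Candidate inversion breakpoints from profile curvature
#'
#' Local maxima of the absolute circular second difference of the fitted
#' curve, ranked by magnitude (ties broken by coordinate), excluding
#' windows around annotated origins, ter sites and barrier elements —
#' genuine kinks of the profile (the fork-trap step, the replication dip
#' at a barrier array) that are not rearrangement junctions.
#'
#' @param s A `smoothed_profile` (typically a light smooth; see
#'   [detect_inversion()]).
#' @param config The matching [chrom_config()].
#' @param k Number of candidates to return.
#' @param exclude_bp Half-width of the exclusion window around annotated
#'   elements, in bp.
#' @return `data.frame` with `position_bp` (bin start) and `curvature`.
#' @export
breakpoint_candidates <- function(s, config, k = 8L, exclude_bp = 20000) {
  stopifnot(inherits(s, "smoothed_profile"), inherits(config, "chrom_config"))
  f <- s$fitted
  n <- length(f)
  w <- s$bin_width
  L <- config$length_bp
  d2 <- abs(f[c(2:n, 1L)] - 2 * f + f[c(n, 1:(n - 1L))])
  locmax <- d2 >= d2[c(2:n, 1L)] & d2 >= d2[c(n, 1:(n - 1L))]
  excl_pos <- c(config$origins$position_bp,
                if (!is.null(config$ter_sites)) config$ter_sites$position_bp,
                if (!is.null(config$barriers)) config$barriers$position_bp)
  starts <- (0:(n - 1L)) * w
  excluded <- rep(FALSE, n)
  for (p in excl_pos)
    excluded <- excluded | circular_distance(starts, rep(p, n), L) <= exclude_bp
  cand <- which(locmax & !excluded)
  o <- order(-d2[cand], cand)
  cand <- cand[o][seq_len(min(k, length(cand)))]
  data.frame(position_bp = (cand - 1L) * w, curvature = d2[cand])
}

#' Detect a gross chromosomal inversion from a marker-frequency profile
#'
#' An inversion shows up as two discontinuities in the replication
#' profile; reversing the inverted segment restores the profile's
#' continuity. The detector (i) lightly smooths the profile (span
#' `light_frac`) to find curvature-based breakpoint candidates, (ii)
#' scores every ordered candidate pair by the reduction in [roughness()]
#' achieved when the clockwise segment between them is reversed, and
#' (iii) refines the best pair by exhaustive +/- `refine_bins` search on
#' the raw enrichment track, where the junctions are sharpest. Because
#' reversing a segment or its complement restores continuity equally, the
#' call is canonicalized to the shorter arc.
#'
#' @param mf An [mfa_profile()].
#' @param config The matching [chrom_config()].
#' @param min_improvement Fraction of the roughness that must be removed
#'   for `called = TRUE`.
#' @param k Number of breakpoint candidates considered.
#' @param light_frac Span of the light candidate-discovery smooth.
#' @param refine_bins Half-width of the exhaustive refinement grid (bins);
#'   wide enough by default to bridge the candidate offset left by the
#'   light smooth.
#' @param exclude_bp Exclusion window around annotated elements.
#' @return An object of class `inversion_call`: `breakpoint_1`,
#'   `breakpoint_2` (bp; clockwise segment from 1 to 2),
#'   `segment_length_bp`, `improvement` (fraction of roughness removed,
#'   on the raw track), `called`, and the candidate table.
#' @export
detect_inversion <- function(mf, config, min_improvement = 0.2, k = 8L,
                             light_frac = 0.02, refine_bins = 25L,
                             exclude_bp = 20000) {
  stopifnot(inherits(mf, "mfa_profile"), inherits(config, "chrom_config"))
  n <- length(mf$enrichment)
  w <- mf$bin_width
  L <- config$length_bp
  light <- loess_periodic(mf, smoothing_params(frac = light_frac))
  cands <- breakpoint_candidates(light, config, k = k, exclude_bp = exclude_bp)

  empty <- structure(list(breakpoint_1 = NA_real_, breakpoint_2 = NA_real_,
                          segment_length_bp = NA_real_, improvement = 0,
                          called = FALSE, candidates = cands),
                     class = "inversion_call")
  if (nrow(cands) < 2L) return(empty)

  # The light smoothing that makes candidate discovery robust also blurs
  # the junctions, so candidates sit on the shoulders of the smoothed
  # jump, up to about half the light window off; and reversing a segment
  # only removes the junction jumps when both breakpoints are essentially
  # exact. The objective is therefore evaluated on the raw enrichment
  # track over a +/- refine_bins grid around every candidate pair.
  # Reversing a circular segment changes only the two boundary adjacencies,
  # so each grid point costs O(1).
  raw <- mf$enrichment
  dif2 <- (raw[c(2:n, 1L)] - raw)^2               # pair (i, i+1), 1-based i
  sum0 <- sum(dif2, na.rm = TRUE)
  npair <- sum(!is.na(dif2))
  r0_raw <- sum0 / npair
  pair_cost <- function(i) dif2[((i - 1L) %% n) + 1L]   # pair (i, i+1)

  cb <- as.integer(cands$position_bp / w)
  grid <- -refine_bins:refine_bins
  best <- c(NA_integer_, NA_integer_); best_delta <- Inf
  for (a in cb) for (b in cb) {
    if (a == b) next
    i1 <- (a + grid) %% n; i2 <- (b + grid) %% n
    x_l0 <- raw[((i1 - 1L) %% n) + 1L]; x_l1 <- raw[i1 + 1L]
    x_r0 <- raw[((i2 - 1L) %% n) + 1L]; x_r1 <- raw[i2 + 1L]
    # after reversing [i1, i2): boundary pairs become
    # (x[i1-1], x[i2-1]) and (x[i1], x[i2])
    new_cost <- outer(x_l0, x_r0, function(p, q) (p - q)^2) +
      outer(x_l1, x_r1, function(p, q) (p - q)^2)
    old_cost <- outer(pair_cost(i1), pair_cost(i2), `+`)
    delta <- new_cost - old_cost
    delta[outer(i1, i2, function(p, q) ((q - p) %% n) < 2L)] <- Inf
    delta[!is.finite(delta)] <- Inf
    j <- arrayInd(which.min(delta), dim(delta))
    if (delta[j] < best_delta) {
      best_delta <- delta[j]
      best <- c(i1[j[1L]], i2[j[2L]])
    }
  }
  b_ref <- best
  imp_ref <- if (is.finite(best_delta)) -best_delta / sum0 else -Inf

  seg_len <- ((b_ref[2L] - b_ref[1L]) %% n) * w
  if (seg_len > L / 2) {                  # canonicalize to the shorter arc
    b_ref <- rev(b_ref)
    seg_len <- L - seg_len
  }
  structure(list(breakpoint_1 = b_ref[1L] * w, breakpoint_2 = b_ref[2L] * w,
                 segment_length_bp = seg_len,
                 improvement = max(0, imp_ref),
                 called = imp_ref >= min_improvement,
                 candidates = cands),
            class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  if (!isTRUE(x$called)) {
    cat(sprintf("<inversion_call> no inversion called (best improvement %.1f%%)\n",
                100 * x$improvement))
  } else {
    cat(sprintf(paste0("<inversion_call> inversion: %.3f -> %.3f Mbp ",
                       "(segment %.0f kb), roughness improvement %.1f%%\n"),
                x$breakpoint_1 / 1e6, x$breakpoint_2 / 1e6,
                x$segment_length_bp / 1000, 100 * x$improvement))
  }
  invisible(x)
}
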