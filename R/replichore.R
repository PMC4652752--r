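#' Locate termination minima of a smoothed replication profile
#'
#' With one origin the global minimum of the LOESS curve is reported; with
#' two origins the circle is split at the origin positions and the fitted
#' minimum within each open inter-origin arc is reported separately (so
#' the terminus-proximal and the inter-origin minima are distinguished, as
#' in a dual-origin strain). Origin bins are never eligible (open arcs).
#' Ties are broken toward the smaller genome coordinate; a minimum sitting
#' on an arc boundary is flagged as suspect.
#'
#' @param s A [loess_periodic()] / [remove_outliers_and_refit()] result.
#' @param config The [chrom_config()] the profile belongs to.
#' @return `data.frame` with one row per arc: `arc_from`, `arc_to`,
#'   `position_bp`, `position_mbp` (bin start, 3 decimals), `value`,
#'   `suspect`.
#' @export
find_termination_minima <- function(s, config) {
  stopifnot(inherits(s, "smoothed_profile"), inherits(config, "chrom_config"))
  n <- length(s$fitted)
  w <- s$bin_width
  L <- config$length_bp
  og <- config$origins
  ob <- as.integer(round(og$position_bp / w)) %% n
  if (nrow(og) > 2L) stop("minima search supports 1 or 2 origins")

  pick_min <- function(bins) {            # bins: 0-based, in arc order
    vals <- s$fitted[bins + 1L]
    v0 <- min(vals)
    cand <- bins[vals <= v0]
    b <- min(cand)                        # tie -> smaller coordinate
    list(bin = b, value = v0,
         suspect = b == bins[1L] || b == bins[length(bins)])
  }

  if (nrow(og) == 1L) {
    bins <- setdiff(0:(n - 1L), ob)
    m <- pick_min(bins)
    res <- data.frame(arc_from = og$name, arc_to = og$name,
                      position_bp = m$bin * w, value = m$value,
                      suspect = FALSE, stringsAsFactors = FALSE)
  } else {
    arc_bins <- function(a, b) {          # open arc, clockwise a -> b
      len <- (b - a) %% n
      if (len < 2L) stop("origins are too close to define an arc")
      ((a + 1:(len - 1L)) %% n)
    }
    res <- NULL
    for (k in 1:2) {
      a <- ob[k]; b <- ob[if (k == 1L) 2L else 1L]
      m <- pick_min(arc_bins(a, b))
      res <- rbind(res, data.frame(
        arc_from = og$name[k], arc_to = og$name[if (k == 1L) 2L else 1L],
        position_bp = m$bin * w, value = m$value, suspect = m$suspect,
        stringsAsFactors = FALSE))
    }
  }
  res$position_mbp <- round(res$position_bp / 1e6, 3)
  res[, c("arc_from", "arc_to", "position_bp", "position_mbp",
          "value", "suspect")]
}

#' Replichore report: minima vs midpoints, shifts and arm lengths
#'
#' Combines termination minima with the arithmetic midpoints of the origin
#' configuration: the signed circular offset from each midpoint to the
#' minimum of its arc (positive = clockwise), and the clockwise /
#' counterclockwise replichore length implied for each origin by the
#' minima. For a single origin at 0.344 Mbp with a minimum at 1.709 Mbp on
#' a 4.64 Mbp genome the arms are 1.365 and 3.275 Mbp — the "1.3 versus
#' 3.3 Mbp" asymmetry of an oriZ-only strain.
#'
#' @param minima A [find_termination_minima()] result (or a `data.frame`
#'   with columns `arc_from`, `arc_to`, `position_bp`).
#' @param config The matching [chrom_config()].
#' @return An object of class `replichore_report` with elements `minima`,
#'   `midpoints` (with `shift_kb` per arc) and `replichore_lengths`
#'   (`data.frame`: origin, clockwise/counterclockwise length in Mbp).
#' @export
replichore_report <- function(minima, config) {
  stopifnot(inherits(config, "chrom_config"))
  L <- config$length_bp
  mp <- arithmetic_midpoints(config)
  key <- paste(minima$arc_from, minima$arc_to)
  mp$minimum_bp <- minima$position_bp[match(paste(mp$arc_from, mp$arc_to), key)]
  mp$shift_kb <- circular_offset(mp$midpoint_bp, mp$minimum_bp, L) / 1000
  mp$midpoint_mbp <- round(mp$midpoint_bp / 1e6, 4)

  og <- config$origins
  rl <- data.frame(origin = og$name,
                   clockwise_mbp = NA_real_, counterclockwise_mbp = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(og))) {
    cw_min <- minima$position_bp[minima$arc_from == og$name[k]]
    ccw_min <- minima$position_bp[minima$arc_to == og$name[k]]
    if (length(cw_min))
      rl$clockwise_mbp[k] <- round(.arc_len(og$position_bp[k], cw_min[1L], L) / 1e6, 3)
    if (length(ccw_min))
      rl$counterclockwise_mbp[k] <- round(.arc_len(ccw_min[1L], og$position_bp[k], L) / 1e6, 3)
  }
  structure(list(minima = minima, midpoints = mp, replichore_lengths = rl,
                 genome_length = L),
            class = "replichore_report")
}

#' @export
print.replichore_report <- function(x, ...) {
  cat("<replichore_report>\n  minima (Mbp):\n")
  for (k in seq_len(nrow(x$minima)))
    cat(sprintf("    %s -> %s arc: %.3f%s\n", x$minima$arc_from[k],
                x$minima$arc_to[k], x$minima$position_bp[k] / 1e6,
                if (isTRUE(x$minima$suspect[k])) " (suspect: at arc boundary)" else ""))
  cat("  midpoints (Mbp) and shifts (kb, clockwise-positive):\n")
  for (k in seq_len(nrow(x$midpoints)))
    cat(sprintf("    %.4f  shift %+.1f kb\n",
                x$midpoints$midpoint_mbp[k], x$midpoints$shift_kb[k]))
  cat("  replichore lengths (Mbp):\n")
  for (k in seq_len(nrow(x$replichore_lengths)))
    cat(sprintf("    %s: cw %.3f / ccw %.3f\n",
                x$replichore_lengths$origin[k],
                x$replichore_lengths$clockwise_mbp[k],
                x$replichore_lengths$counterclockwise_mbp[k]))
  invisible(x)
}

#' Gradient-deviation scores for annotated regions
#'
#' Forks slowed inside a highly transcribed region steepen the replication
#' profile locally, so the magnitude of the log2 profile gradient inside
#' the region, relative to the typical gradient of the enclosing
#' replichore arm, measures the slowdown: `score = mean(|g|) in region /
#' median(|g|) in arm`, where `g` is the central-difference gradient of
#' `log2(fitted)` and the arm baseline excludes every annotated region.
#' On a pure exponential gradient the score is 1; a head-on rrn zone that
#' halves the local fork speed scores about 2.
#'
#' @param s A `smoothed_profile`.
#' @param config The matching [chrom_config()].
#' @param regions Regions to score: `data.frame` with `name`, `start_bp`,
#'   `end_bp` (defaults to the configuration's slow zones).
#' @param minima Optional precomputed [find_termination_minima()] result;
#'   computed from `s` otherwise. Origins and minima bound the arms.
#' @return `data.frame` with `name`, `score` (`NA` with a warning where
#'   the arm gradient is below epsilon), `n_bins`.
#' @export
gradient_deviation_scores <- function(s, config, regions = config$slow_zones,
                                      minima = NULL) {
  stopifnot(inherits(s, "smoothed_profile"), inherits(config, "chrom_config"))
  if (is.null(regions) || !nrow(regions)) stop("no regions to score")
  if (is.null(minima)) minima <- find_termination_minima(s, config)
  n <- length(s$fitted)
  w <- s$bin_width
  L <- config$length_bp
  eps <- 1e-6

  lf <- log2(pmax(s$fitted, .Machine$double.xmin))
  g <- (lf[c(2:n, 1L)] - lf[c(n, 1:(n - 1L))]) / 2   # per-bin log2 units
  ag <- abs(g)

  bound_bp <- sort(unique(c(config$origins$position_bp, minima$position_bp)))
  bound_bin <- sort(unique(as.integer(round(bound_bp / w)) %% n))
  starts <- (0:(n - 1L)) * w

  arm_id <- rep(NA_integer_, n)           # arm = interval between boundaries
  nb <- length(bound_bin)
  for (k in seq_len(nb)) {
    a <- bound_bin[k]; b <- bound_bin[if (k == nb) 1L else k + 1L]
    len <- (b - a) %% n
    if (len > 1L) arm_id[((a + 1:(len - 1L)) %% n) + 1L] <- k
  }

  in_any_region <- rep(FALSE, n)
  reg_bins <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    inz <- in_circular_interval(starts, regions$start_bp[k],
                                regions$end_bp[k], L)
    reg_bins[[k]] <- which(inz)
    in_any_region <- in_any_region | inz
  }

  score <- rep(NA_real_, nrow(regions))
  for (k in seq_len(nrow(regions))) {
    rb <- reg_bins[[k]]
    if (!length(rb)) next
    arms <- arm_id[rb]
    arm <- as.integer(names(sort(table(arms), decreasing = TRUE))[1L])
    if (length(unique(stats::na.omit(arms))) > 1L)
      warning("region '", regions$name[k],
              "' spans an arm boundary; scored against its majority arm")
    base <- which(arm_id == arm & !in_any_region)
    med <- stats::median(ag[base])
    if (!is.finite(med) || med < eps) {
      warning("arm gradient below epsilon for region '", regions$name[k],
              "': score undefined")
      next
    }
    score[k] <- mean(ag[rb]) / med
  }
  data.frame(name = regions$name, score = score,
             n_bins = vapply(reg_bins, length, 0L),
             stringsAsFactors = FALSE)
}
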