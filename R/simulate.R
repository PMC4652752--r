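#' Simulation parameters for the replication-fork forward model
#'
#' Bundles the kinetic and sequencing-noise parameters used by
#' [simulate_replication_timing()], [timing_to_copy_number()] and
#' [sample_count_pair()].
#'
#' Defaults follow the biology of fast-growing *E. coli*: forks move at up
#' to 1000 nt/s, wild-type-like cultures double every ~20 min and a strain
#' replicating from the ectopic origin alone every ~40 min. The `rpo_star`
#' flag emulates an RNA-polymerase-destabilising point mutation by moving
#' every slow-zone speed factor toward 1 by the relief fraction.
#'
#' @param fork_speed_bp_per_s Unimpeded fork speed (bp/s).
#' @param doubling_time_min Population doubling time (minutes). 19.9 is
#'   wild-type-like, 39.8 matches a strain replicating from oriZ only.
#' @param mean_depth_per_bin Mean sequencing depth per bin for count draws.
#' @param bias_sd_log SD of the per-bin lognormal mappability bias, shared
#'   between the exponential and stationary samples. 0 disables bias.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (`var = mu + dispersion *
#'   mu^2`); required when `noise_model = "negative_binomial"`.
#' @param seed Integer seed; every random draw derives a deterministic
#'   substream from it. `NULL` uses the session RNG stream.
#' @param tus_active If `FALSE` all ter sites are transparent (a tus-null
#'   background).
#' @param rpo_star If `TRUE`, slow-zone factors `f` are replaced by
#'   `1 - rpo_relief * (1 - f)`.
#' @param rpo_relief Fraction of the slow-zone speed deficit removed by
#'   `rpo_star`.
#' @param bin_width_bp Bin width used when discretising the genome.
#' @return A list of class `sim_params`.
#' @export
simulation_params <- function(fork_speed_bp_per_s = 1000,
                              doubling_time_min = 19.9,
                              mean_depth_per_bin = 100,
                              bias_sd_log = 0,
                              noise_model = c("poisson", "negative_binomial"),
                              dispersion = NULL,
                              seed = NULL,
                              tus_active = TRUE,
                              rpo_star = FALSE,
                              rpo_relief = 0.5,
                              bin_width_bp = 1000) {
  noise_model <- match.arg(noise_model)
  stopifnot(fork_speed_bp_per_s > 0, doubling_time_min > 0,
            mean_depth_per_bin > 0, bias_sd_log >= 0, bin_width_bp > 0,
            rpo_relief >= 0, rpo_relief <= 1)
  if (noise_model == "negative_binomial" &&
      (is.null(dispersion) || dispersion <= 0))
    stop("negative_binomial noise needs a positive dispersion")
  structure(list(fork_speed_bp_per_s = fork_speed_bp_per_s,
                 doubling_time_min = doubling_time_min,
                 mean_depth_per_bin = mean_depth_per_bin,
                 bias_sd_log = bias_sd_log,
                 noise_model = noise_model, dispersion = dispersion,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 tus_active = isTRUE(tus_active),
                 rpo_star = isTRUE(rpo_star), rpo_relief = rpo_relief,
                 bin_width_bp = bin_width_bp),
            class = "sim_params")
}

# evaluate fun() under a deterministic substream of `seed`, restoring the
# caller's RNG state afterwards; seed NULL -> use the session stream as-is
.with_substream <- function(seed, op, fun) {
  if (is.null(seed)) return(fun())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + as.integer(op))
  fun()
}

# per-bin speed factors for each fork direction; a fork is "head-on" in a
# zone when its direction opposes the direction of transcription
.bin_speed_factors <- function(config, n, w, params) {
  f_cw <- rep(1, n); f_ccw <- rep(1, n)
  sz <- config$slow_zones
  if (!is.null(sz) && nrow(sz)) {
    starts <- (0:(n - 1)) * w
    for (k in seq_len(nrow(sz))) {
      ho <- sz$head_on_factor[k]; co <- sz$codirectional_factor[k]
      if (params$rpo_star) {
        ho <- 1 - params$rpo_relief * (1 - ho)
        co <- 1 - params$rpo_relief * (1 - co)
      }
      inz <- in_circular_interval(starts, sz$start_bp[k], sz$end_bp[k],
                                  config$length_bp)
      if (sz$transcription_direction[k] == "clockwise") {
        f_cw[inz] <- pmin(f_cw[inz], co); f_ccw[inz] <- pmin(f_ccw[inz], ho)
      } else {
        f_cw[inz] <- pmin(f_cw[inz], ho); f_ccw[inz] <- pmin(f_ccw[inz], co)
      }
    }
  }
  list(cw = f_cw, ccw = f_ccw)
}

#' Simulate replication timing on a circular chromosome
#'
#' Event-driven kinetics of replication forks: every origin fires at t = 0
#' and launches one clockwise and one counterclockwise fork moving at
#' `fork_speed_bp_per_s`, locally rescaled inside transcription slow zones
#' (head-on or co-directional factor depending on fork orientation). A fork
#' reaching a polar ter site whose orientation blocks it halts — with
#' probability equal to the site's efficiency — until the converging fork
#' arrives and the two fuse; with `tus_active = FALSE` all ter sites are
#' transparent. Barrier elements impose a fixed pause. Converging forks
#' meeting inside a bin fuse at the exact interpolated position.
#'
#' `t_rep[i]` is the time (seconds) at which the start coordinate of bin
#' `i` is replicated; it is 0 exactly at origin bins. Origins are snapped
#' to bin starts.
#'
#' @param config A [chrom_config()].
#' @param params A [simulation_params()].
#' @param bin_width Bin width in bp (defaults to `params$bin_width_bp`).
#' @return An object of class `replication_timing`: fields `t_rep`
#'   (seconds per bin), `bin_width`, `genome_length`, `fusions`
#'   (`data.frame` of fusion position/time), and `events` (per-fork log of
#'   starts, blocks, passes, pauses and fusions).
#' @examples
#' cfg <- chrom_config(10000, origins = c(ori = 0))
#' tm <- simulate_replication_timing(cfg, simulation_params(fork_speed_bp_per_s = 1000))
#' tm$t_rep  # 0,1,...,5,...,1 seconds
#' @export
simulate_replication_timing <- function(config, params = simulation_params(),
                                        bin_width = params$bin_width_bp) {
  stopifnot(inherits(config, "chrom_config"), inherits(params, "sim_params"))
  L <- config$length_bp
  w <- bin_width
  n <- as.integer(ceiling(L / w))
  if (n < 4L) stop("genome must span at least 4 bins")
  v <- params$fork_speed_bp_per_s
  fac <- .bin_speed_factors(config, n, w, params)
  dt_cw <- w / (v * fac$cw); dt_ccw <- w / (v * fac$ccw)

  # ter sites and barriers snapped to bin-start edges
  block_cw <- rep(NA_real_, n); block_ccw <- rep(NA_real_, n)
  ter_name_cw <- rep(NA_character_, n); ter_name_ccw <- rep(NA_character_, n)
  if (params$tus_active && !is.null(config$ter_sites)) {
    ts <- config$ter_sites
    for (k in seq_len(nrow(ts))) {
      e <- as.integer(round(ts$position_bp[k] / w)) %% n
      if (ts$block[k] == "blocks_clockwise") {
        block_cw[e + 1L] <- ts$efficiency[k]; ter_name_cw[e + 1L] <- ts$name[k]
      } else {
        block_ccw[e + 1L] <- ts$efficiency[k]; ter_name_ccw[e + 1L] <- ts$name[k]
      }
    }
  }
  pause_at <- rep(0, n)
  if (!is.null(config$barriers)) {
    bs <- config$barriers
    for (k in seq_len(nrow(bs))) {
      e <- as.integer(round(bs$position_bp[k] / w)) %% n
      pause_at[e + 1L] <- pause_at[e + 1L] + bs$pause_s[k]
    }
  }

  # fork table; edge e sits at coordinate e*w, bins are [e*w, (e+1)*w)
  og <- config$origins
  nf <- 2L * nrow(og)
  fk <- list(
    origin = rep(og$name, each = 2L),
    dir    = rep(c(1L, -1L), nrow(og)),           # +1 clockwise
    edge   = rep(as.integer(round(og$position_bp / w)) %% n, each = 2L),
    time   = rep(0, nf),
    state  = rep("active", nf)                    # active | blocked | done
  )
  if (any(abs(og$position_bp - round(og$position_bp / w) * w) > 1e-9))
    warning("origin position(s) snapped to bin starts")

  t_rep <- rep(NA_real_, n)
  claimed <- rep(FALSE, n)
  fus_pos <- numeric(0); fus_time <- numeric(0)
  ev <- list(time = numeric(0), fork = character(0), type = character(0),
             position_bp = numeric(0))
  log_ev <- function(t, f, type, pos) {
    ev$time[length(ev$time) + 1L] <<- t
    ev$fork[length(ev$fork) + 1L] <<- f
    ev$type[length(ev$type) + 1L] <<- type
    ev$position_bp[length(ev$position_bp) + 1L] <<- pos
  }
  fork_label <- function(i) paste0(fk$origin[i], ifelse(fk$dir[i] > 0, "+", "-"))
  for (i in seq_len(nf)) log_ev(0, fork_label(i), "start", fk$edge[i] * w)

  target_bin <- function(i) {
    if (fk$dir[i] > 0L) fk$edge[i] else (fk$edge[i] - 1L) %% n
  }
  eff_draws <- if (is.null(params$seed)) NULL else
    .with_substream(params$seed, 11L, function() stats::runif(4L * n + 64L))
  draw_i <- 0L
  pass_check <- function(eff) {
    if (eff >= 1) return(FALSE)           # always blocked
    if (eff <= 0) return(TRUE)            # transparent
    draw_i <<- draw_i + 1L
    u <- if (is.null(eff_draws)) stats::runif(1L) else
      eff_draws[((draw_i - 1L) %% length(eff_draws)) + 1L]
    u >= eff
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * n + 100L * nf)
      stop("internal error: simulation failed to make progress")
    act <- which(fk$state == "active")
    if (!length(act)) break
    i <- act[which.min(fk$time[act])]
    tb <- target_bin(i)

    # a converging fork (active or blocked) headed for the same bin?
    opp <- NA_integer_
    for (j in seq_len(nf)) {
      if (j != i && fk$state[j] != "done" && fk$dir[j] != fk$dir[i] &&
          target_bin(j) == tb) { opp <- j; break }
    }

    if (claimed[tb + 1L]) {
      # ran into already-replicated DNA: terminate at the current edge
      x <- fk$edge[i] * w
      fk$state[i] <- "done"
      fus_pos <- c(fus_pos, x); fus_time <- c(fus_time, fk$time[i])
      log_ev(fk$time[i], fork_label(i), "fusion", x)
      # a blocked fork waiting face-to-face at this edge fuses too
      for (j in seq_len(nf)) {
        if (fk$state[j] == "blocked" && fk$edge[j] == fk$edge[i] &&
            fk$dir[j] != fk$dir[i]) {
          fk$state[j] <- "done"
          log_ev(fk$time[i], fork_label(j), "fusion", x)
        }
      }
      next
    }

    if (!is.na(opp)) {
      # exact meet inside bin tb
      cwf <- if (fk$dir[i] > 0L) i else opp
      ccwf <- if (fk$dir[i] > 0L) opp else i
      x0 <- tb * w; x1 <- x0 + w
      v1 <- if (fk$state[cwf] == "blocked") 0 else v * fac$cw[tb + 1L]
      v2 <- if (fk$state[ccwf] == "blocked") 0 else v * fac$ccw[tb + 1L]
      t1 <- fk$time[cwf]; t2 <- fk$time[ccwf]
      if (v1 + v2 <= 0) stop("two blocked forks face an unreplicated bin: ",
                             "region unreachable")
      tm <- (w + v1 * t1 + v2 * t2) / (v1 + v2)
      xm <- x0 + v1 * (tm - t1)
      claimed[tb + 1L] <- TRUE
      if (is.na(t_rep[tb + 1L]))
        t_rep[tb + 1L] <- if (v1 > 0) t1 else tm  # time x0 is replicated
      fk$state[c(cwf, ccwf)] <- "done"
      fus_pos <- c(fus_pos, xm %% L); fus_time <- c(fus_time, tm)
      log_ev(tm, fork_label(cwf), "fusion", xm %% L)
      log_ev(tm, fork_label(ccwf), "fusion", xm %% L)
      next
    }

    # plain traversal of bin tb
    claimed[tb + 1L] <- TRUE
    if (fk$dir[i] > 0L) {
      if (is.na(t_rep[tb + 1L])) t_rep[tb + 1L] <- fk$time[i]
      fk$time[i] <- fk$time[i] + dt_cw[tb + 1L]
      fk$edge[i] <- (fk$edge[i] + 1L) %% n
    } else {
      fk$time[i] <- fk$time[i] + dt_ccw[tb + 1L]
      fk$edge[i] <- (fk$edge[i] - 1L) %% n
      if (is.na(t_rep[tb + 1L])) t_rep[tb + 1L] <- fk$time[i]
    }
    # arrival at the new edge: a blocking ter site arrests the fork there
    # (the bin ahead then inherits its time from the converging fork);
    # otherwise a clockwise fork timestamps the bin it is about to enter
    # before any barrier pause is served at this edge
    e <- fk$edge[i]
    eff <- if (fk$dir[i] > 0L) block_cw[e + 1L] else block_ccw[e + 1L]
    blocked_here <- FALSE
    if (!is.na(eff)) {
      nm <- if (fk$dir[i] > 0L) ter_name_cw[e + 1L] else ter_name_ccw[e + 1L]
      if (pass_check(eff)) {
        log_ev(fk$time[i], fork_label(i), paste0("pass:", nm), e * w)
      } else {
        fk$state[i] <- "blocked"
        blocked_here <- TRUE
        log_ev(fk$time[i], fork_label(i), paste0("block:", nm), e * w)
      }
    }
    if (!blocked_here) {
      if (fk$dir[i] > 0L && is.na(t_rep[e + 1L]))
        t_rep[e + 1L] <- fk$time[i]
      if (pause_at[e + 1L] > 0) {
        log_ev(fk$time[i], fork_label(i), "pause", e * w)
        fk$time[i] <- fk$time[i] + pause_at[e + 1L]
      }
    }
    if (!any(fk$state == "active") && any(fk$state == "blocked")) {
      if (anyNA(t_rep))
        stop("all remaining forks are blocked with unreplicated bins: ",
             "region unreachable under this trap configuration")
      fk$state[fk$state == "blocked"] <- "done"   # degenerate: nothing left
    }
  }
  if (anyNA(t_rep))
    stop("unreplicated bins remain: region unreachable under this configuration")

  structure(list(bin_width = w, genome_length = L, t_rep = t_rep,
                 fusions = data.frame(position_bp = fus_pos, time_s = fus_time),
                 events = as.data.frame(ev, stringsAsFactors = FALSE),
                 origins = og, params = params),
            class = "replication_timing")
}

#' @export
print.replication_timing <- function(x, ...) {
  cat(sprintf("<replication_timing> %d bins of %d bp, %d origin(s)\n",
              length(x$t_rep), x$bin_width, nrow(x$origins)))
  cat(sprintf("  max t_rep: %.1f s; fusions at %s Mbp\n", max(x$t_rep),
              paste(sprintf("%.3f", sort(unique(x$fusions$position_bp)) / 1e6),
                    collapse = ", ")))
  invisible(x)
}

#' Convert replication timing to steady-state relative copy number
#'
#' In an asynchronous exponential population every cell-cycle age is
#' present with exponential weighting, so a locus replicated at time `t`
#' after initiation has relative abundance `M = 2^(-t / tau_d)` with
#' `tau_d` the doubling time. Origin bins (`t = 0`) have `M = 1`; `M`
#' decreases monotonically in `t_rep`.
#'
#' @param timing A [simulate_replication_timing()] result, or a numeric
#'   vector of per-bin replication times in seconds.
#' @param doubling_time_min Doubling time in minutes (> 0).
#' @return Numeric vector of per-bin relative copy numbers in `(0, 1]`.
#' @export
timing_to_copy_number <- function(timing, doubling_time_min) {
  if (!is.numeric(doubling_time_min) || doubling_time_min <= 0)
    stop("doubling time must be positive")
  t_rep <- if (inherits(timing, "replication_timing")) timing$t_rep else timing
  if (any(!is.finite(t_rep))) stop("t_rep must be finite")
  2^(-t_rep / (doubling_time_min * 60))
}

#' Draw a matched exponential/stationary sequencing-count pair
#'
#' Emulates the sequencing layer of a marker-frequency experiment: a
#' per-bin multiplicative mappability bias (lognormal, shared between the
#' two samples) modulates both libraries; the exponential-phase sample has
#' expected counts proportional to `copy_number * bias`, the non-replicating
#' stationary control proportional to `bias` alone. Counts are Poisson or
#' negative-binomial. With a `seed` in `params` the draw is reproducible.
#'
#' @param copy_number Noise-free per-bin relative copy number
#'   (see [timing_to_copy_number()]).
#' @param params A [simulation_params()].
#' @param bin_width Bin width in bp for the returned coverage objects.
#' @return List with elements `exponential` and `stationary`, both
#'   [binned_coverage()] objects, plus `bias` (the shared per-bin factor).
#' @export
sample_count_pair <- function(copy_number, params = simulation_params(),
                              bin_width = params$bin_width_bp) {
  stopifnot(is.numeric(copy_number), all(copy_number > 0))
  n <- length(copy_number)
  L <- n * bin_width
  bias <- if (params$bias_sd_log > 0)
    .with_substream(params$seed, 1L,
                    function() stats::rlnorm(n, 0, params$bias_sd_log))
  else rep(1, n)
  mu_exp <- params$mean_depth_per_bin * copy_number * bias / mean(copy_number * bias)
  mu_stat <- params$mean_depth_per_bin * bias / mean(bias)
  draw <- function(mu, op) .with_substream(params$seed, op, function() {
    if (params$noise_model == "poisson") stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / params$dispersion)
  })
  list(exponential = binned_coverage(draw(mu_exp, 2L), bin_width, L,
                                     sample_label = "exponential"),
       stationary = binned_coverage(draw(mu_stat, 3L), bin_width, L,
                                    sample_label = "stationary"),
       bias = bias)
}

#' Invert a circular segment of a per-bin track
#'
#' Reverses, in place, the bins on the clockwise segment from `b1` to `b2`
#' — the read-depth signature of a chromosomal inversion when reads from a
#' rearranged genome are mapped onto the reference arrangement. Applying
#' the same inversion twice restores the input.
#'
#' @param track A numeric per-bin vector, a [binned_coverage()] or an
#'   [marker_frequency()] profile.
#' @param b1,b2 Breakpoints in bp (for numeric vectors with
#'   `bin_width = 1`, in bins). The segment runs clockwise from `b1`
#'   (inclusive) to `b2` (exclusive).
#' @param bin_width Bin width in bp (numeric method only; default 1).
#' @param strict If `TRUE`, breakpoints off bin boundaries are an error;
#'   otherwise they are snapped to the nearest boundary with a warning.
#' @return The track with the segment reversed, same class as the input.
#' @examples
#' apply_inversion(0:9, 2, 6)  # 0 1 5 4 3 2 6 7 8 9
#' @export
apply_inversion <- function(track, b1, b2, ...) UseMethod("apply_inversion")

.inv_bins <- function(b, bin_width, n, strict, what) {
  ix <- b / bin_width
  if (abs(ix - round(ix)) > 1e-9) {
    if (strict) stop(what, " is not on a bin boundary")
    warning(what, " snapped to the nearest bin boundary")
  }
  as.integer(round(ix)) %% n
}

.inv_index <- function(n, b1, b2, bin_width, strict) {
  i1 <- .inv_bins(b1, bin_width, n, strict, "breakpoint b1")
  i2 <- .inv_bins(b2, bin_width, n, strict, "breakpoint b2")
  if (i1 == i2) stop("breakpoints must differ")
  len <- (i2 - i1) %% n
  seg <- ((i1 + 0:(len - 1L)) %% n) + 1L
  idx <- seq_len(n)
  idx[seg] <- rev(idx[seg])
  idx
}

#' @rdname apply_inversion
#' @export
apply_inversion.numeric <- function(track, b1, b2, bin_width = 1,
                                    strict = FALSE, ...) {
  idx <- .inv_index(length(track), b1, b2, bin_width, strict)
  track[idx]
}

#' @rdname apply_inversion
#' @export
apply_inversion.binned_coverage <- function(track, b1, b2, strict = FALSE, ...) {
  idx <- .inv_index(length(track$counts), b1, b2, track$bin_width, strict)
  track$counts <- track$counts[idx]
  track
}

#' @rdname apply_inversion
#' @export
apply_inversion.mfa_profile <- function(track, b1, b2, strict = FALSE, ...) {
  idx <- .inv_index(length(track$enrichment), b1, b2, track$bin_width, strict)
  track$enrichment <- track$enrichment[idx]
  track$mask <- track$mask[idx]
  track$mask_reason <- track$mask_reason[idx]
  track
}

#' Simulate a viable-count growth curve
#'
#' Deterministic multi-subpopulation exponential growth,
#' `N(t) = N0 * sum_k f_k * 2^(t / tau_k)`, optionally corrupted by
#' multiplicative lognormal counting noise. A small fast-growing
#' subpopulation reproduces the biphasic curves seen when suppressor
#' mutants overgrow a slow parent strain. Samples every 30 min by default.
#'
#' @param subpopulations `data.frame` with columns `fraction` (initial
#'   fractions, summing to 1) and `doubling_time_min`.
#' @param n0_cfu_per_ml Total initial titre.
#' @param t_max_min,step_min Sampling span and interval (minutes).
#' @param noise_sd_log SD of lognormal noise on counts (0 = none).
#' @param seed Seed for the noise draw.
#' @return An object of class `growth_curve` with `times_min`,
#'   `cfu_per_ml` and the generating `subpopulations`.
#' @export
simulate_growth_curve <- function(subpopulations =
                                    data.frame(fraction = 1,
                                               doubling_time_min = 19.9),
                                  n0_cfu_per_ml = 1e7,
                                  t_max_min = 480, step_min = 30,
                                  noise_sd_log = 0, seed = NULL) {
  sp <- as.data.frame(subpopulations)
  stopifnot(all(c("fraction", "doubling_time_min") %in% names(sp)),
            nrow(sp) >= 1, all(sp$fraction > 0), all(sp$doubling_time_min > 0))
  if (abs(sum(sp$fraction) - 1) > 1e-8)
    stop("subpopulation fractions must sum to 1")
  times <- seq(0, t_max_min, by = step_min)
  cfu <- vapply(times, function(t)
    n0_cfu_per_ml * sum(sp$fraction * 2^(t / sp$doubling_time_min)), 0)
  if (noise_sd_log > 0)
    cfu <- cfu * .with_substream(seed, 21L, function()
      stats::rlnorm(length(cfu), 0, noise_sd_log))
  structure(list(times_min = times, cfu_per_ml = cfu, subpopulations = sp),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d samples, %g-%g min, %d subpopulation(s)\n",
              length(x$times_min), min(x$times_min), max(x$times_min),
              nrow(x$subpopulations)))
  invisible(x)
}
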