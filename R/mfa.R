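#' Per-bin read counts on a circular genome
#'
#' Container for uniquely-mapping read (tag) counts in fixed-width windows
#' — 1 kb by convention. Counts are assumed to come from uniquely mapped
#' reads; alignment and filtering are upstream of this package.
#'
#' @param counts Nonnegative per-bin counts; length must equal
#'   `ceiling(genome_length_bp / bin_width_bp)`.
#' @param bin_width_bp Bin width in bp.
#' @param genome_length_bp Circular genome length in bp.
#' @param sample_label Free-text label (e.g. `"exponential"`).
#' @return An object of class `binned_coverage`.
#' @export
binned_coverage <- function(counts, bin_width_bp = 1000, genome_length_bp,
                            sample_label = "") {
  stopifnot(is.numeric(counts), bin_width_bp > 0, genome_length_bp > 0)
  if (any(!is.finite(counts) | counts < 0)) stop("counts must be >= 0")
  n_exp <- as.integer(ceiling(genome_length_bp / bin_width_bp))
  if (length(counts) != n_exp)
    stop("expected ", n_exp, " bins for this genome, got ", length(counts))
  structure(list(counts = as.numeric(counts), bin_width = bin_width_bp,
                 genome_length = genome_length_bp,
                 sample_label = sample_label),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("<binned_coverage> %s%d bins of %d bp, total %s reads\n",
              if (nzchar(x$sample_label)) paste0(x$sample_label, ": ") else "",
              length(x$counts), x$bin_width,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Bin interval depth records into fixed windows
#'
#' Apportions each record's per-bp value to the bins it overlaps, in
#' proportion to overlap length; records with `end > L` wrap through the
#' coordinate origin and are split. Bin totals are rounded half-up to
#' integers at the end.
#'
#' @param records `data.frame` with columns `start`, `end` (0-based
#'   half-open, bp) and `value` (per-bp depth). Records must not overlap.
#' @param bin_width Bin width in bp.
#' @param genome_length Genome length in bp.
#' @param sample_label Label passed through to the result.
#' @return A [binned_coverage()].
#' @examples
#' bin_coverage(data.frame(start = 0, end = 2000, value = 1), 1000, 10000)
#' @export
bin_coverage <- function(records, bin_width, genome_length, sample_label = "") {
  L <- genome_length
  n <- as.integer(ceiling(L / bin_width))
  acc <- rep(0, n)
  if (NROW(records)) {
    stopifnot(all(c("start", "end", "value") %in% names(records)))
    if (any(records$value < 0)) stop("negative depth values are not allowed")
    if (any(records$start < 0 | records$start >= L))
      stop("record starts must lie in [0, L)")
    if (any(records$end <= records$start))
      stop("records must have end > start")
    if (any(records$end > 2 * L))
      stop("record extends more than a full wrap beyond the genome")
    # split wrap-around records at L
    wrap <- records$end > L
    if (any(wrap)) {
      tail_part <- records[wrap, , drop = FALSE]
      tail_part$start <- 0
      tail_part$end <- records$end[wrap] - L
      records$end[wrap] <- L
      records <- rbind(records, tail_part)
    }
    o <- order(records$start)
    rs <- records$start[o]; re <- records$end[o]
    if (any(rs[-1] < re[-length(re)])) stop("records overlap")
    for (k in seq_along(rs)) {
      b0 <- floor(rs[k] / bin_width); b1 <- ceiling(re[k] / bin_width) - 1
      for (b in b0:b1) {
        ov <- min(re[k], (b + 1) * bin_width) - max(rs[k], b * bin_width)
        acc[b + 1L] <- acc[b + 1L] + records$value[o[k]] * ov
      }
    }
  }
  binned_coverage(floor(acc + 0.5), bin_width, L, sample_label)
}

#' Marker-frequency profile from an exponential/stationary count pair
#'
#' The marker frequency of bin *i* is the library-size-normalized ratio of
#' exponential-phase to stationary-phase counts,
#' `E_i = (c_i / sum(c)) / (s_i / sum(s))`, with totals taken over unmasked
#' bins. Dividing by the non-replicating stationary control cancels
#' per-bin mappability bias shared between the samples, so `E` reflects
#' relative copy number in the replicating population. Bins with a zero
#' control count (and any user-excluded bins) are masked and propagate as
#' masked through smoothing and minima searches.
#'
#' @param exponential,stationary [binned_coverage()] objects with identical
#'   bin structure.
#' @param exclude_bins Optional integer vector of 1-based bin indices to
#'   mask (e.g. deleted regions).
#' @return An object of class `mfa_profile`: `enrichment` (per-bin value,
#'   `NA` where masked), `mask`, `mask_reason`, `bin_width`,
#'   `genome_length`.
#' @examples
#' ex <- binned_coverage(c(20, 10), 1000, 2000)
#' st <- binned_coverage(c(10, 10), 1000, 2000)
#' marker_frequency(ex, st)$enrichment  # 4/3, 2/3
#' @export
marker_frequency <- function(exponential, stationary, exclude_bins = NULL) {
  stopifnot(inherits(exponential, "binned_coverage"),
            inherits(stationary, "binned_coverage"))
  if (exponential$bin_width != stationary$bin_width ||
      length(exponential$counts) != length(stationary$counts))
    stop("samples must share the same bin structure")
  c_i <- exponential$counts; s_i <- stationary$counts
  n <- length(c_i)
  mask <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  if (!is.null(exclude_bins)) {
    mask[exclude_bins] <- TRUE
    reason[exclude_bins] <- "user_excluded"
  }
  zero <- !mask & s_i == 0
  mask[zero] <- TRUE
  reason[zero] <- "zero_control"
  if (sum(c_i[!mask]) == 0 || sum(s_i[!mask]) == 0)
    stop("zero total counts over unmasked bins")
  enr <- rep(NA_real_, n)
  enr[!mask] <- (c_i[!mask] / sum(c_i[!mask])) / (s_i[!mask] / sum(s_i[!mask]))
  structure(list(enrichment = enr, mask = mask, mask_reason = reason,
                 bin_width = exponential$bin_width,
                 genome_length = exponential$genome_length),
            class = "mfa_profile")
}

#' Construct a marker-frequency profile directly from per-bin values
#'
#' Convenience constructor used for noise-free simulated tracks or
#' externally computed enrichments.
#'
#' @param enrichment Per-bin nonnegative values (`NA` = masked).
#' @param bin_width_bp Bin width in bp.
#' @param genome_length_bp Genome length in bp (default
#'   `length(enrichment) * bin_width_bp`).
#' @return An `mfa_profile`.
#' @export
mfa_profile <- function(enrichment, bin_width_bp = 1000,
                        genome_length_bp = length(enrichment) * bin_width_bp) {
  mask <- !is.finite(enrichment)
  if (any(enrichment[!mask] < 0)) stop("enrichment must be >= 0")
  enrichment[mask] <- NA_real_
  structure(list(enrichment = enrichment, mask = mask,
                 mask_reason = ifelse(mask, "user_excluded", NA_character_),
                 bin_width = bin_width_bp, genome_length = genome_length_bp),
            class = "mfa_profile")
}

#' @export
print.mfa_profile <- function(x, ...) {
  cat(sprintf("<mfa_profile> %d bins of %d bp (%d masked)\n",
              length(x$enrichment), x$bin_width, sum(x$mask)))
  q <- stats::quantile(x$enrichment[!x$mask], c(0, .5, 1))
  cat(sprintf("  enrichment: min %.3f, median %.3f, max %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' @export
plot.mfa_profile <- function(x, smoothed = NULL, ...) {
  pos <- (seq_along(x$enrichment) - 1) * x$bin_width / 1e6
  graphics::plot(pos, x$enrichment, pch = ".", cex = 2, col = "grey40",
                 xlab = "Position (Mbp)", ylab = "Marker frequency", ...)
  if (!is.null(smoothed))
    graphics::lines(pos, smoothed$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}
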