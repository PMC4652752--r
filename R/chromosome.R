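#' Circular genome configuration
#'
#' Data model for a circular bacterial chromosome: its length plus the
#' annotated elements the replication-profile analysis and the fork
#' simulator need — replication origins, polar `ter` sites bound by Tus,
#' transcription "slow zones" (typically `rrn` operons), hard barrier
#' elements (e.g. a `tetO` operator array) and the `dif` dimer-resolution
#' site.
#'
#' All coordinates are 0-based base pairs in `[0, length_bp)`; circular
#' intervals with `start_bp > end_bp` wrap through the origin of the
#' coordinate system. File I/O ([read_annotation()], [write_annotation()])
#' converts to and from 1-based closed GFF3 intervals.
#'
#' @param length_bp Genome length in bp (positive integer).
#' @param origins `data.frame` with columns `name`, `position_bp`, or a
#'   named numeric vector of positions.
#' @param ter_sites `data.frame` with columns `name`, `position_bp`,
#'   `block` (`"blocks_clockwise"` or `"blocks_counterclockwise"`) and
#'   optionally `efficiency` (fraction in `[0,1]`, default 1), or `NULL`.
#' @param slow_zones `data.frame` with columns `name`, `start_bp`, `end_bp`,
#'   `transcription_direction` (`"clockwise"`/`"counterclockwise"`),
#'   `head_on_factor` in `(0,1]` and optionally `codirectional_factor`
#'   (default 1), or `NULL`. A fork crossing the zone against the direction
#'   of transcription moves at `head_on_factor` times full speed.
#' @param barriers `data.frame` with columns `name`, `position_bp`,
#'   `pause_s` (pause imposed on a crossing fork, seconds), or `NULL`.
#' @param dif Position of the `dif` site in bp (informational), or `NULL`.
#' @return An object of class `chrom_config`.
#' @examples
#' cfg <- chrom_config(4640000, origins = c(oriC = 3923000, oriZ = 344000))
#' arithmetic_midpoints(cfg)
#' @export
chrom_config <- function(length_bp, origins, ter_sites = NULL,
                         slow_zones = NULL, barriers = NULL, dif = NULL) {
  stopifnot(is.numeric(length_bp), length(length_bp) == 1L, length_bp > 0)
  length_bp <- as.numeric(length_bp)

  origins <- .as_positions_df(origins, "origins")
  if (nrow(origins) < 1L) stop("at least one origin is required")
  if (anyDuplicated(origins$name)) stop("origin names must be unique")
  .check_pos(origins$position_bp, length_bp, "origin")

  if (!is.null(ter_sites) && nrow(ter_sites)) {
    ter_sites <- as.data.frame(ter_sites, stringsAsFactors = FALSE)
    need <- c("name", "position_bp", "block")
    if (!all(need %in% names(ter_sites)))
      stop("ter_sites needs columns: ", paste(need, collapse = ", "))
    if (is.null(ter_sites$efficiency)) ter_sites$efficiency <- 1
    ok <- ter_sites$block %in% c("blocks_clockwise", "blocks_counterclockwise")
    if (!all(ok)) stop("ter polarity must be blocks_clockwise or blocks_counterclockwise")
    if (any(ter_sites$efficiency < 0 | ter_sites$efficiency > 1))
      stop("ter efficiency must be in [0,1]")
    .check_pos(ter_sites$position_bp, length_bp, "ter site")
  } else ter_sites <- NULL

  if (!is.null(slow_zones) && nrow(slow_zones)) {
    slow_zones <- as.data.frame(slow_zones, stringsAsFactors = FALSE)
    need <- c("name", "start_bp", "end_bp", "transcription_direction", "head_on_factor")
    if (!all(need %in% names(slow_zones)))
      stop("slow_zones needs columns: ", paste(need, collapse = ", "))
    if (is.null(slow_zones$codirectional_factor)) slow_zones$codirectional_factor <- 1
    ok <- slow_zones$transcription_direction %in% c("clockwise", "counterclockwise")
    if (!all(ok)) stop("transcription_direction must be clockwise or counterclockwise")
    f <- c(slow_zones$head_on_factor, slow_zones$codirectional_factor)
    if (any(f <= 0 | f > 1)) stop("slow-zone speed factors must be in (0,1]")
    .check_pos(slow_zones$start_bp, length_bp, "slow zone")
    .check_pos(slow_zones$end_bp, length_bp, "slow zone")
  } else slow_zones <- NULL

  if (!is.null(barriers) && nrow(barriers)) {
    barriers <- as.data.frame(barriers, stringsAsFactors = FALSE)
    need <- c("name", "position_bp", "pause_s")
    if (!all(need %in% names(barriers)))
      stop("barriers needs columns: ", paste(need, collapse = ", "))
    if (any(barriers$pause_s < 0)) stop("barrier pause must be >= 0")
    .check_pos(barriers$position_bp, length_bp, "barrier")
  } else barriers <- NULL

  if (!is.null(dif)) .check_pos(dif, length_bp, "dif")

  structure(
    list(length_bp = length_bp, origins = origins, ter_sites = ter_sites,
         slow_zones = slow_zones, barriers = barriers, dif = dif),
    class = "chrom_config")
}

.as_positions_df <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("name", "position_bp") %in% names(x)))
      stop(what, " needs columns name, position_bp")
    data.frame(name = as.character(x$name),
               position_bp = as.numeric(x$position_bp),
               stringsAsFactors = FALSE)
  } else if (is.numeric(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("origin", seq_along(x))
    data.frame(name = nm, position_bp = as.numeric(x), stringsAsFactors = FALSE)
  } else stop(what, " must be a data.frame or a named numeric vector")
}

.check_pos <- function(p, L, what) {
  if (any(!is.finite(p) | p < 0 | p >= L))
    stop(what, " position out of range [0, ", format(L, scientific = FALSE), ")")
  invisible(TRUE)
}

#' @export
print.chrom_config <- function(x, ...) {
  cat(sprintf("<chrom_config> circular genome, %s bp\n",
              format(x$length_bp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  origins:    %s\n",
              paste(sprintf("%s @ %.3f Mbp", x$origins$name,
                            x$origins$position_bp / 1e6), collapse = ", ")))
  cat(sprintf("  ter sites:  %d   slow zones: %d   barriers: %d\n",
              NROW(x$ter_sites), NROW(x$slow_zones), NROW(x$barriers)))
  if (!is.null(x$dif)) cat(sprintf("  dif:        %.3f Mbp\n", x$dif / 1e6))
  invisible(x)
}

#' Shortest arc between two positions on a circle
#'
#' @param a,b Positions in `[0, L)` (vectorized).
#' @param L Circle length.
#' @return Shortest arc length(s), in `[0, L/2]`.
#' @examples
#' circular_distance(1, 9, 10)   # 2, through the wrap
#' @export
circular_distance <- function(a, b, L) {
  stopifnot(L > 0)
  if (any(a < 0 | a >= L | b < 0 | b >= L)) stop("positions must lie in [0, L)")
  d <- abs(a - b)
  pmin(d, L - d)
}

#' Signed clockwise offset from one position to another
#'
#' Offset in `(-L/2, L/2]`: positive when `to` lies clockwise (increasing
#' coordinate) of `from` along the shorter arc.
#'
#' @inheritParams circular_distance
#' @param from,to Positions in `[0, L)`.
#' @export
circular_offset <- function(from, to, L) {
  stopifnot(L > 0)
  ((to - from + L / 2) %% L) - L / 2
}

#' Arithmetic midpoints between replication origins
#'
#' For a single origin the midpoint is its antipode, `(a + L/2) mod L`. For
#' two origins `a`, `b` there are two midpoints, `((a+b)/2) mod L` and the
#' same plus `L/2`; each bisects one of the two inter-origin arcs and is the
#' point both forks would reach simultaneously at equal, constant speed.
#'
#' @param origins A `chrom_config`, or a numeric vector of 1 or 2 origin
#'   positions (bp).
#' @param length_bp Genome length in bp (ignored when `origins` is a
#'   `chrom_config`).
#' @return `data.frame` with columns `midpoint_bp`, `arc_from`, `arc_to`
#'   (names of the origins bounding the clockwise arc the midpoint bisects).
#' @examples
#' arithmetic_midpoints(c(oriC = 3923000, oriZ = 344000), 4640000)
#' @export
arithmetic_midpoints <- function(origins, length_bp = NULL) {
  if (inherits(origins, "chrom_config")) {
    length_bp <- origins$length_bp
    pos <- origins$origins$position_bp
    names(pos) <- origins$origins$name
  } else {
    pos <- origins
    if (is.null(names(pos))) names(pos) <- paste0("origin", seq_along(pos))
  }
  stopifnot(is.numeric(length_bp), length_bp > 0)
  L <- as.numeric(length_bp)
  .check_pos(pos, L, "origin")
  if (length(pos) == 1L) {
    return(data.frame(midpoint_bp = (pos[[1L]] + L / 2) %% L,
                      arc_from = names(pos), arc_to = names(pos),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  if (length(pos) != 2L)
    stop("arithmetic midpoints are defined for 1 or 2 origins, got ", length(pos))
  m1 <- (sum(pos) / 2) %% L
  m2 <- (m1 + L / 2) %% L
  a <- pos[[1L]]; b <- pos[[2L]]
  res <- data.frame(midpoint_bp = c(m1, m2),
                    arc_from = NA_character_, arc_to = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in 1:2) {
    if (in_circular_interval(res$midpoint_bp[k], a, b, L)) {
      res$arc_from[k] <- names(pos)[1L]; res$arc_to[k] <- names(pos)[2L]
    } else {
      res$arc_from[k] <- names(pos)[2L]; res$arc_to[k] <- names(pos)[1L]
    }
  }
  res
}

#' Membership in a circular half-open interval
#'
#' Tests whether `x` lies in the clockwise interval `[start, end)`; when
#' `start > end` the interval wraps through 0 (needed, e.g., for the arc
#' from the rrnCABE cluster through the origin of coordinates).
#'
#' @param x Position(s) in `[0, L)`.
#' @param start,end Interval bounds in `[0, L)`.
#' @param L Circle length.
#' @export
in_circular_interval <- function(x, start, end, L) {
  stopifnot(L > 0)
  if (start <= end) x >= start & x < end
  else x >= start | x < end
}

# length of the clockwise arc from a to b
.arc_len <- function(a, b, L) (b - a) %% L
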