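#' Read per-bin coverage from bedGraph or two-column TSV
#'
#' bedGraph records (`chrom start end value`, 0-based half-open) are
#' apportioned to fixed bins with [bin_coverage()]; records whose `end`
#' runs past the genome length wrap through the coordinate origin and are
#' split. The TSV form is one line per bin: `bin_start<TAB>count`.
#' Malformed or out-of-order lines are reported with their line number.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"tsv"`.
#' @param bin_width Bin width in bp.
#' @param genome_length Genome length in bp; required for bedGraph,
#'   inferred from the bin count for TSV when omitted.
#' @param sample_label Label stored in the result.
#' @return A [binned_coverage()].
#' @export
read_coverage <- function(path, format = c("auto", "bedgraph", "tsv"),
                          bin_width = 1000, genome_length = NULL,
                          sample_label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lnum <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  bad <- function(i, why) stop(sprintf("%s, line %d: %s", path, lnum[i], why),
                               call. = FALSE)
  if (format == "bedgraph") {
    if (is.null(genome_length))
      stop("genome_length is required for bedGraph input")
    nf <- lengths(fields)
    if (any(nf != 4L)) bad(which(nf != 4L)[1L], "expected 4 tab-separated fields")
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    for (col in list(start, end, value))
      if (anyNA(col)) bad(which(is.na(col))[1L], "non-numeric field")
    if (any(start < 0 | start >= genome_length))
      bad(which(start < 0 | start >= genome_length)[1L], "start out of range")
    if (any(end <= start)) bad(which(end <= start)[1L], "end must exceed start")
    if (any(value < 0)) bad(which(value < 0)[1L], "negative value")
    if (length(start) > 1L && any(diff(start) <= 0))
      bad(which(diff(start) <= 0)[1L] + 1L, "records not sorted by start")
    ovl <- which(end[-length(end)] > start[-1L] &
                   end[-length(end)] <= genome_length)
    if (length(ovl)) bad(ovl[1L] + 1L, "record overlaps the previous one")
    bin_coverage(data.frame(start = start, end = end, value = value),
                 bin_width, genome_length, sample_label)
  } else {
    nf <- lengths(fields)
    if (any(nf != 2L)) bad(which(nf != 2L)[1L], "expected 2 tab-separated fields")
    pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
    cnt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    if (anyNA(pos)) bad(which(is.na(pos))[1L], "non-numeric position")
    if (anyNA(cnt)) bad(which(is.na(cnt))[1L], "non-numeric count")
    expect_pos <- (seq_along(pos) - 1L) * bin_width
    if (any(pos != expect_pos))
      bad(which(pos != expect_pos)[1L],
          sprintf("bin start does not match %d bp binning", bin_width))
    if (is.null(genome_length)) genome_length <- length(cnt) * bin_width
    binned_coverage(cnt, bin_width, genome_length, sample_label)
  }
}

#' Write a marker-frequency profile as TSV
#'
#' One line per bin: `start`, `end`, `value` (6 significant digits, `NA`
#' where masked) and `mask` (the mask reason, `.` for unmasked bins).
#' [read_profile()] restores the object.
#'
#' @param profile An [mfa_profile()].
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "mfa_profile"))
  n <- length(profile$enrichment)
  w <- profile$bin_width
  val <- ifelse(profile$mask, "NA",
                as.character(signif(profile$enrichment, 6)))
  reason <- ifelse(profile$mask, profile$mask_reason, ".")
  writeLines(c("start\tend\tvalue\tmask",
               sprintf("%d\t%d\t%s\t%s", (0:(n - 1L)) * w, (1:n) * w,
                       val, reason)),
             path)
  invisible(path)
}

#' @rdname write_profile
#' @return `read_profile` returns an [mfa_profile()].
#' @export
read_profile <- function(path) {
  tb <- utils::read.delim(path, na.strings = "NA")
  w <- tb$end[1L] - tb$start[1L]
  p <- mfa_profile(tb$value, bin_width_bp = w,
                   genome_length_bp = max(tb$end))
  p$mask_reason[p$mask] <- tb$mask[p$mask]
  p
}

.feature_types <- c("origin", "ter", "rrn", "barrier", "dif")

#' Read a chromosome annotation into a configuration
#'
#' GFF3 (1-based closed intervals, converted to the internal 0-based
#' coordinates) with feature types `origin`, `ter`, `rrn`, `barrier` and
#' `dif`. ter polarity comes from the `block` attribute
#' (`blocks_clockwise` / `blocks_counterclockwise`; required), fork-pass
#' efficiency from `efficiency` (default 1). `rrn` features become
#' transcription slow zones: the strand gives the direction of
#' transcription (`+` = clockwise), speed factors come from
#' `head_on_factor` and `codirectional_factor` attributes. `barrier`
#' features carry `pause_s`. Genome length is taken from the
#' `##sequence-region` directive. A 6-column TSV alternative
#' (`type name start_bp end_bp orientation value`, 0-based, with a
#' `chromosome` row giving the length) is also supported.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A [chrom_config()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") .read_annotation_gff3(path) else .read_annotation_tsv(path)
}

.read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3",
                            sequenceRegionsAsSeqinfo = TRUE)
  L <- GenomeInfoDb::seqlengths(gr)[1L]
  if (is.na(L))
    stop("GFF3 must carry a ##sequence-region directive with the genome length")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else
    paste0(typ, seq_along(gr))
  st0 <- GenomicRanges::start(gr) - 1L          # to 0-based
  en0 <- GenomicRanges::end(gr)                 # closed -> half-open
  getnum <- function(field, default) {
    if (field %in% names(md)) {
      v <- suppressWarnings(as.numeric(as.character(md[[field]])))
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }

  sel <- typ == "origin"
  origins <- data.frame(name = nm[sel], position_bp = st0[sel],
                        stringsAsFactors = FALSE)

  sel <- typ == "ter"
  ter <- NULL
  if (any(sel)) {
    blk <- if ("block" %in% names(md)) as.character(md$block)[sel] else
      rep(NA_character_, sum(sel))
    if (anyNA(blk))
      stop("ter feature without a block polarity attribute: ",
           paste(nm[sel][is.na(blk)], collapse = ", "))
    ter <- data.frame(name = nm[sel], position_bp = st0[sel], block = blk,
                      efficiency = getnum("efficiency", 1)[sel],
                      stringsAsFactors = FALSE)
  }

  sel <- typ == "rrn"
  zones <- NULL
  if (any(sel)) {
    strand <- as.character(GenomicRanges::strand(gr))[sel]
    if (any(strand == "*"))
      stop("rrn feature without a strand (direction of transcription)")
    zones <- data.frame(
      name = nm[sel], start_bp = st0[sel], end_bp = en0[sel],
      transcription_direction = ifelse(strand == "+", "clockwise",
                                       "counterclockwise"),
      head_on_factor = getnum("head_on_factor", 0.25)[sel],
      codirectional_factor = getnum("codirectional_factor", 0.9)[sel],
      stringsAsFactors = FALSE)
  }

  sel <- typ == "barrier"
  barriers <- if (any(sel))
    data.frame(name = nm[sel], position_bp = st0[sel],
               pause_s = getnum("pause_s", 0)[sel], stringsAsFactors = FALSE)

  sel <- typ == "dif"
  dif <- if (any(sel)) st0[sel][1L]

  chrom_config(as.numeric(L), origins, ter, zones, barriers, dif)
}

.read_annotation_tsv <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("type", "name", "start_bp", "end_bp",
                                        "orientation", "value"))
  Lrow <- tb$type == "chromosome"
  if (!any(Lrow)) stop("TSV annotation needs a 'chromosome' row with the length")
  L <- tb$end_bp[Lrow][1L]
  tb <- tb[!Lrow, , drop = FALSE]
  pick <- function(ty) tb[tb$type == ty, , drop = FALSE]
  og <- pick("origin")
  tr <- pick("ter")
  ter <- if (nrow(tr)) {
    if (any(!tr$orientation %in% c("blocks_clockwise", "blocks_counterclockwise")))
      stop("ter rows need blocks_clockwise/blocks_counterclockwise orientation")
    data.frame(name = tr$name, position_bp = tr$start_bp,
               block = tr$orientation,
               efficiency = ifelse(is.na(as.numeric(tr$value)), 1,
                                   as.numeric(tr$value)),
               stringsAsFactors = FALSE)
  }
  rr <- pick("rrn")
  zones <- if (nrow(rr)) {
    fx <- strsplit(as.character(rr$value), ";", fixed = TRUE)
    data.frame(name = rr$name, start_bp = rr$start_bp, end_bp = rr$end_bp,
               transcription_direction = rr$orientation,
               head_on_factor = vapply(fx, function(v) as.numeric(v[1L]), 0),
               codirectional_factor =
                 vapply(fx, function(v)
                   if (length(v) > 1L) as.numeric(v[2L]) else 1, 0),
               stringsAsFactors = FALSE)
  }
  br <- pick("barrier")
  barriers <- if (nrow(br))
    data.frame(name = br$name, position_bp = br$start_bp,
               pause_s = as.numeric(br$value), stringsAsFactors = FALSE)
  df <- pick("dif")
  dif <- if (nrow(df)) df$start_bp[1L]
  chrom_config(L, data.frame(name = og$name, position_bp = og$start_bp,
                             stringsAsFactors = FALSE),
               ter, zones, barriers, dif)
}

#' Write a chromosome configuration as GFF3
#'
#' Inverse of [read_annotation()]; coordinates are converted back to
#' 1-based closed intervals and the genome length is recorded in the
#' `##sequence-region` directive. Slow zones wrapping through coordinate
#' zero cannot be represented in GFF3 and are an error.
#'
#' @param config A [chrom_config()].
#' @param path Output file.
#' @export
write_annotation <- function(config, path) {
  stopifnot(inherits(config, "chrom_config"))
  rows <- list()
  add <- function(type, name, s0, e0, strand = "*", attrs = character(0)) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, name = name, start = s0 + 1, end = e0, strand = strand,
      attrs = paste(attrs, collapse = ";"), stringsAsFactors = FALSE)
  }
  og <- config$origins
  for (k in seq_len(nrow(og)))
    add("origin", og$name[k], og$position_bp[k], og$position_bp[k] + 1)
  if (!is.null(config$ter_sites)) {
    ts <- config$ter_sites
    for (k in seq_len(nrow(ts)))
      add("ter", ts$name[k], ts$position_bp[k], ts$position_bp[k] + 1,
          attrs = c(sprintf("block=%s", ts$block[k]),
                    sprintf("efficiency=%g", ts$efficiency[k])))
  }
  if (!is.null(config$slow_zones)) {
    sz <- config$slow_zones
    if (any(sz$end_bp < sz$start_bp))
      stop("slow zones wrapping through 0 cannot be written as GFF3; split them")
    for (k in seq_len(nrow(sz)))
      add("rrn", sz$name[k], sz$start_bp[k], sz$end_bp[k],
          strand = if (sz$transcription_direction[k] == "clockwise") "+" else "-",
          attrs = c(sprintf("head_on_factor=%g", sz$head_on_factor[k]),
                    sprintf("codirectional_factor=%g",
                            sz$codirectional_factor[k])))
  }
  if (!is.null(config$barriers)) {
    bs <- config$barriers
    for (k in seq_len(nrow(bs)))
      add("barrier", bs$name[k], bs$position_bp[k], bs$position_bp[k] + 1,
          attrs = sprintf("pause_s=%g", bs$pause_s[k]))
  }
  if (!is.null(config$dif)) add("dif", "dif", config$dif, config$dif + 1)
  tb <- do.call(rbind, rows)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region chromosome 1 %d",
                     as.integer(config$length_bp)),
             sprintf("chromosome\trepliprofile\t%s\t%d\t%d\t.\t%s\t.\tName=%s%s",
                     tb$type, as.integer(tb$start), as.integer(tb$end),
                     tb$strand, tb$name,
                     ifelse(nzchar(tb$attrs), paste0(";", tb$attrs), "")))
  writeLines(lines, path)
  invisible(path)
}

#' The bundled dual-origin E. coli chromosome model
#'
#' A 4.64 Mbp circular chromosome with the native origin at 3.923 Mbp
#' (oriC) and the ectopic origin at 0.344 Mbp (oriZ), the dif site, ten
#' polar ter sites (A-J) and the seven rrn operons (A-E, G, H) as
#' transcription slow zones. rrnH sits at 0.229 Mbp and the rrnCABE
#' cluster spans 3.94-4.21 Mbp; ter and rrnD/rrnG coordinates are
#' literature-scale approximations (the analysis depends on their
#' polarity semantics, not their exact positions).
#'
#' @param origins Which origins to keep: `"both"`, `"oriC"` (wild-type
#'   like) or `"oriZ"` (ectopic-origin-only like).
#' @return A [chrom_config()].
#' @export
ecoli_model <- function(origins = c("both", "oriC", "oriZ")) {
  origins <- match.arg(origins)
  path <- system.file("extdata", "ecoli_dual_origin_model.gff3",
                      package = "repliprofile", mustWork = TRUE)
  cfg <- read_annotation(path)
  if (origins != "both")
    cfg$origins <- cfg$origins[cfg$origins$name == origins, , drop = FALSE]
  cfg
}
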