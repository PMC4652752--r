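#' Run the full replication-profile analysis
#'
#' Smooths a marker-frequency profile with the periodic LOESS (including
#' the squared-residual outlier pass), locates the termination minima,
#' builds the replichore report (midpoints, shifts, arm lengths), scores
#' gradient deviations at annotated slow zones and optionally screens for
#' a gross inversion.
#'
#' @param mf An [mfa_profile()].
#' @param config A [chrom_config()].
#' @param params A [smoothing_params()].
#' @param strain Free-text strain label carried into the report.
#' @param scan_inversion If `TRUE`, run [detect_inversion()].
#' @return An object of class `mfa_report` bundling the smoothed profile
#'   and every analysis product.
#' @export
analyze_replication_profile <- function(mf, config,
                                        params = smoothing_params(),
                                        strain = "",
                                        scan_inversion = FALSE) {
  s <- remove_outliers_and_refit(mf, params)
  minima <- find_termination_minima(s, config)
  rep <- replichore_report(minima, config)
  dev <- if (!is.null(config$slow_zones))
    gradient_deviation_scores(s, config, minima = minima)
  inv <- if (scan_inversion) detect_inversion(mf, config)
  structure(list(strain = strain, smoothed = s, minima = minima,
                 replichores = rep, deviation_scores = dev,
                 inversion = inv,
                 params = list(frac = params$frac,
                               outlier_threshold = params$outlier_threshold,
                               refit_passes = params$refit_passes,
                               bin_width = mf$bin_width),
                 config_digest = .config_digest(config),
                 version = as.character(utils::packageVersion("repliprofile")),
                 schema = 1L),
            class = "mfa_report")
}

# order-stable digest of the configuration (no external hash dependency)
.config_digest <- function(config) {
  s <- paste(
    config$length_bp,
    paste(config$origins$name, config$origins$position_bp, collapse = ","),
    if (!is.null(config$ter_sites))
      paste(config$ter_sites$name, config$ter_sites$position_bp,
            config$ter_sites$block, collapse = ","),
    if (!is.null(config$slow_zones))
      paste(config$slow_zones$name, config$slow_zones$start_bp,
            config$slow_zones$end_bp, collapse = ","),
    sep = "|")
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.mfa_report <- function(x, ...) {
  cat(sprintf("<mfa_report>%s schema %d, config %s\n",
              if (nzchar(x$strain)) paste0(" strain ", x$strain, ",") else "",
              x$schema, x$config_digest))
  print(x$replichores)
  if (!is.null(x$deviation_scores)) {
    cat("  gradient deviation scores:\n")
    for (k in seq_len(nrow(x$deviation_scores)))
      cat(sprintf("    %s: %.2f\n", x$deviation_scores$name[k],
                  x$deviation_scores$score[k]))
  }
  if (!is.null(x$inversion)) print(x$inversion)
  invisible(x)
}

#' Serialize / restore an analysis report as JSON
#'
#' The JSON twin of the replichore table: minima, midpoints, shifts, arm
#' lengths, deviation scores, inversion call, parameters and version,
#' under a versioned schema. `read_report()` restores the numeric
#' content losslessly (the smoothed profile itself is not serialized;
#' use [write_profile()] for tracks).
#'
#' @param report An [analyze_replication_profile()] result.
#' @param path Output (input) file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mfa_report"))
  payload <- list(
    schema = report$schema,
    version = report$version,
    strain = report$strain,
    config_digest = report$config_digest,
    params = report$params,
    minima = report$minima,
    midpoints = report$replichores$midpoints,
    replichore_lengths = report$replichores$replichore_lengths,
    deviation_scores = report$deviation_scores,
    inversion = if (!is.null(report$inversion))
      report$inversion[c("breakpoint_1", "breakpoint_2", "segment_length_bp",
                         "improvement", "called")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
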