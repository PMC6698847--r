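#' Write a chromatogram to tidy CSV
#'
#' Columns: `time_min`, `component`, `concentration_g_per_L`, `modifier_M`,
#' `flow_mL_min`.
#'
#' @param chrom an [chromatogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE)
  invisible(path)
}

#' Read a chromatogram from tidy CSV
#'
#' Expects the columns written by [write_chromatogram_csv()]; unknown extra
#' columns are preserved in `$meta$extra`.
#'
#' @param path input file path.
#' @return An [chromatogram()] object.
#' @export
read_chromatogram_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("time_min", "component", "concentration_g_per_L")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("missing required column(s) in %s: %s", path,
          paste(missing, collapse = ", "))
  comps <- unique(df$component)
  first <- df$component == comps[1L]
  t <- df$time_min[first]
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stopf("non-monotone time grid in %s (around data line %d)", path, bad)
  }
  conc <- vapply(comps, function(cp) {
    sub <- df[df$component == cp, ]
    if (nrow(sub) != length(t) || any(sub$time_min != t))
      stopf("component '%s' is not on the shared time grid in %s", cp, path)
    sub$concentration_g_per_L
  }, numeric(length(t)))
  colnames(conc) <- comps
  extra_cols <- setdiff(names(df),
                        c(required, "modifier_M", "flow_mL_min"))
  chromatogram(time = t, conc = conc,
               modifier = if ("modifier_M" %in% names(df))
                 df$modifier_M[first] else NULL,
               flow = if ("flow_mL_min" %in% names(df))
                 df$flow_mL_min[first] else NULL,
               meta = if (length(extra_cols))
                 list(extra = df[first, extra_cols, drop = FALSE])
               else list())
}

#' Write a tracer curve to two-column CSV
#'
#' @param curve a [tracer_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracer_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_min = curve$time, signal = curve$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a tracer curve from two-column CSV
#'
#' @param path input file path (columns `time_min`, `signal`).
#' @param flow volumetric flow, mL/min.
#' @param tracer_mw optional tracer molecular weight, Da.
#' @return A [tracer_curve()].
#' @export
read_tracer_csv <- function(path, flow, tracer_mw = NA_real_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("time_min", "signal") %in% names(df)))
    stopf("tracer CSV %s needs columns time_min, signal", path)
  tracer_curve(df$time_min, df$signal, flow = flow, tracer_mw = tracer_mw)
}

#' Write a run manifest
#'
#' Records enough to re-run a deterministic pipeline bit-identically: the
#' MD5 of the configuration file, package version, seed, timestamps and the
#' input/output paths.
#'
#' @param path manifest output path (JSON).
#' @param config_file configuration file the run consumed (hashed), or `NULL`.
#' @param seed integer seed used (or `NA`).
#' @param inputs,outputs character vectors of file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config_file = NULL, seed = NA,
                           inputs = character(0), outputs = character(0)) {
  manifest <- list(
    package = "memchrom",
    version = as.character(utils::packageVersion("memchrom")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_file = config_file,
    config_md5 = if (!is.null(config_file) && file.exists(config_file))
      unname(tools::md5sum(config_file)) else NA,
    inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
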