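#' Chromatogram container
#'
#' Outlet concentration traces of a chromatographic run on a strictly
#' increasing time grid, together with the modifier and flow traces.
#'
#' @param time time grid, min (strictly increasing).
#' @param conc numeric matrix (time x component) of outlet concentrations,
#'   g/L; column names identify the components.
#' @param modifier modifier concentration trace, mol/L.
#' @param flow flow trace, mL/min.
#' @param meta optional list of extra metadata (extra detector columns read
#'   from files end up here).
#' @return An object of class `mc_chromatogram`.
#' @export
chromatogram <- function(time, conc, modifier = NULL, flow = NULL,
                         meta = list()) {
  conc <- as.matrix(conc)
  nt <- length(time)
  if (nt < 1L) stopf("empty time grid")
  if (any(diff(time) <= 0)) stopf("'time' must be strictly increasing")
  if (nrow(conc) != nt) stopf("'conc' must have one row per time point")
  if (any(!is.finite(conc))) stopf("concentrations must be finite")
  if (min(conc) < -1e-8)
    stopf("negative concentrations beyond solver tolerance (min %.3g)",
          min(conc))
  modifier <- modifier %||% rep(0, nt)
  flow <- flow %||% rep(NA_real_, nt)
  if (length(modifier) != nt || length(flow) != nt)
    stopf("'modifier' and 'flow' must match the time grid length")
  if (is.null(colnames(conc)))
    colnames(conc) <- paste0("comp", seq_len(ncol(conc)))
  structure(list(time = as.numeric(time), conc = conc,
                 modifier = as.numeric(modifier), flow = as.numeric(flow),
                 meta = meta),
            class = "mc_chromatogram")
}

#' @export
print.mc_chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d points over %.4g min, components: %s\n",
              length(x$time), max(x$time) - min(x$time),
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mc_chromatogram <- function(x, ...) {
  data.frame(time_min = rep(x$time, ncol(x$conc)),
             component = rep(colnames(x$conc), each = length(x$time)),
             concentration_g_per_L = as.numeric(x$conc),
             modifier_M = rep(x$modifier, ncol(x$conc)),
             flow_mL_min = rep(x$flow, ncol(x$conc)))
}

#' @export
plot.mc_chromatogram <- function(x, show_modifier = TRUE, ...) {
  comps <- colnames(x$conc)
  graphics::matplot(x$time, x$conc, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "concentration (g/L)", ...)
  graphics::legend("topright", legend = comps, col = seq_along(comps),
                   lty = 1, bty = "n")
  if (show_modifier && any(x$modifier > 0)) {
    graphics::par(new = TRUE)
    graphics::plot(x$time, x$modifier, type = "l", lty = 3, col = "grey40",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("modifier (M)", side = 4, line = 2, cex = 0.8)
  }
  invisible(x)
}

## pooled volume (mL) and per-component mass (mg) over a time window
pool_window <- function(chrom, t_from, t_to) {
  t <- chrom$time
  sel <- t >= t_from & t <= t_to
  if (sum(sel) < 2L)
    return(list(volume = 0,
                mass = stats::setNames(numeric(ncol(chrom$conc)),
                                       colnames(chrom$conc))))
  ts <- t[sel]
  vol <- trapz(ts, chrom$flow[sel])
  mass <- vapply(seq_len(ncol(chrom$conc)), function(k)
    trapz(ts, chrom$flow[sel] * chrom$conc[sel, k]), numeric(1))
  list(volume = vol,
       mass = stats::setNames(mass, colnames(chrom$conc)))
}

#' First time a component's outlet concentration crosses a threshold
#'
#' Linear interpolation between reporting points; `NA` if the threshold is
#' never reached.
#'
#' @param chrom an [chromatogram()].
#' @param component column name or index.
#' @param threshold concentration threshold, g/L.
#' @return Crossing time in min, or `NA`.
#' @export
breakthrough_time <- function(chrom, component, threshold) {
  y <- chrom$conc[, component]
  above <- which(y >= threshold)
  if (!length(above)) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(chrom$time[1L])
  t0 <- chrom$time[i - 1L]; t1 <- chrom$time[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}
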