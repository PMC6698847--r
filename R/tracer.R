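#' Tracer outlet curve
#'
#' @param time time grid in minutes, strictly increasing.
#' @param signal detector signal (>= 0, arbitrary units).
#' @param flow volumetric flow in mL/min (> 0).
#' @param tracer_mw optional tracer molecular weight, Da (bookkeeping).
#' @return An object of class `mc_tracer_curve`.
#' @export
tracer_curve <- function(time, signal, flow, tracer_mw = NA_real_) {
  if (length(time) != length(signal))
    stopf("'time' and 'signal' must have equal length")
  if (any(diff(time) <= 0))
    stopf("'time' must be strictly increasing")
  if (any(!is.finite(signal)))
    stopf("'signal' must be finite")
  check_number(flow, "flow", lower = 0, strict_lower = TRUE)
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 flow = flow, tracer_mw = tracer_mw),
            class = "mc_tracer_curve")
}

#' Moment analysis of a tracer curve
#'
#' Computes the mean residence time and variance of a residence-time
#' distribution by trapezoidal quadrature on the given grid:
#' `tbar = int t s dt / int s dt`,
#' `sigma2 = int (t - tbar)^2 s dt / int s dt`.
#' The signal is baseline-subtracted first (baseline = median of the first
#' 5\% of points), since detector offsets otherwise bias the second moment.
#'
#' @param curve an [tracer_curve()] object (a single-point "curve" is
#'   treated as a Dirac spike).
#' @param baseline_fraction fraction of leading points used for the
#'   baseline estimate (set to 0 to disable subtraction).
#' @return List with `t_mean` (min), `variance` (min^2), and
#'   `norm_variance` (`variance / t_mean^2`, dimensionless).
#' @export
moments <- function(curve, baseline_fraction = 0.05) {
  if (!inherits(curve, "mc_tracer_curve"))
    stopf("'curve' must be a tracer_curve")
  t <- curve$time
  s <- curve$signal
  if (length(t) == 1L)
    return(list(t_mean = t, variance = 0, norm_variance = 0))
  if (baseline_fraction > 0) {
    k <- max(1L, floor(length(s) * baseline_fraction))
    s <- s - stats::median(s[seq_len(k)])
  }
  s <- pmax(s, 0)
  area <- trapz(t, s)
  if (area <= 0)
    stopf("tracer signal has zero area after baseline subtraction")
  t_mean <- trapz(t, t * s) / area
  variance <- trapz(t, (t - t_mean)^2 * s) / area
  list(t_mean = t_mean, variance = variance,
       norm_variance = variance / t_mean^2)
}

#' Module voidage from tracer residence times
#'
#' `eps = (t_mean - t_instrument) * flow / Vm`: the accessible module volume
#' (total residence volume minus the extra-column instrument volume) as a
#' fraction of the nominal module volume.
#'
#' @param t_mean total mean residence time, min.
#' @param t_instrument mean residence time of the instruments without the
#'   module (blank run), min.
#' @param flow volumetric flow, mL/min (> 0).
#' @param Vm module volume, mL (> 0).
#' @return Voidage (dimensionless).
#' @export
voidage <- function(t_mean, t_instrument, flow, Vm) {
  check_number(t_mean, "t_mean", lower = 0)
  check_number(t_instrument, "t_instrument", lower = 0)
  check_number(flow, "flow", lower = 0, strict_lower = TRUE)
  check_number(Vm, "Vm", lower = 0, strict_lower = TRUE)
  if (t_mean < t_instrument)
    stopf(paste("t_mean (%g min) < t_instrument (%g min):",
                "blank run mis-assigned?"), t_mean, t_instrument)
  (t_mean - t_instrument) * flow / Vm
}

## closed-vessel Danckwerts relation: normalized variance as a function of
## x = Dax / (v * l)
closed_vessel_variance <- function(x) 2 * x - 2 * x^2 * (1 - exp(-1 / x))

#' Axial dispersion from RTD variance (closed-vessel boundary conditions)
#'
#' Inverts the closed-vessel relation
#' `sigma2/tbar2 = 2 x - 2 x^2 (1 - exp(-1/x))`, `x = Dax/(v l)`,
#' by a bracketed root search on `log10(x)`.  The log-spaced bracket spans
#' `x` from 1e-12 to 1e6, tolerating the many orders of magnitude over which
#' per-zone dispersion coefficients vary in practice.
#'
#' @param norm_variance normalized variance `sigma^2 / tbar^2`; must lie in
#'   (0, 1), the attainable range of the closed-vessel relation.
#' @param v flow velocity, cm/s (or any unit; `Dax` comes back in `v*l`
#'   units).
#' @param l characteristic length, cm.
#' @return Dax in `v * l` units (cm^2/s for cm/s and cm inputs).
#' @export
dax_from_variance_closed <- function(norm_variance, v, l) {
  check_number(v, "v", lower = 0, strict_lower = TRUE)
  check_number(l, "l", lower = 0, strict_lower = TRUE)
  if (!is_number(norm_variance) || norm_variance <= 0 || norm_variance >= 1)
    stopf(paste("normalized variance %g is outside (0, 1), the attainable",
                "range under closed-vessel boundary conditions"),
          norm_variance)
  f <- function(lx) closed_vessel_variance(10^lx) - norm_variance
  root <- stats::uniroot(f, interval = c(-12, 6), tol = 1e-14)
  10^root$root * v * l
}

#' Axial dispersion from RTD variance (open-vessel boundary conditions)
#'
#' Solves the open-vessel relation `sigma2/tbar2 = 2 x + 8 x^2` in closed
#' form (positive root), `x = Dax/(v l)`.
#'
#' @inheritParams dax_from_variance_closed
#' @param norm_variance normalized variance (> 0).
#' @return Dax in `v * l` units.
#' @export
dax_from_variance_open <- function(norm_variance, v, l) {
  check_number(v, "v", lower = 0, strict_lower = TRUE)
  check_number(l, "l", lower = 0, strict_lower = TRUE)
  check_number(norm_variance, "norm_variance", lower = 0)
  x <- (-2 + sqrt(4 + 32 * norm_variance)) / 16
  x * v * l
}

#' Bodenstein number
#'
#' `Bo = u l / Dax`, the ratio of convective to dispersive transport.
#'
#' @param u linear velocity, cm/s.
#' @param l characteristic length, cm.
#' @param Dax axial dispersion coefficient, cm^2/s.
#' @return Bodenstein number (dimensionless).
#' @export
bodenstein <- function(u, l, Dax) {
  check_number(u, "u", lower = 0, strict_lower = TRUE)
  check_number(l, "l", lower = 0, strict_lower = TRUE)
  check_number(Dax, "Dax", lower = 0, strict_lower = TRUE)
  u * l / Dax
}

#' Classify the flow regime from the Bodenstein number
#'
#' Below the critical value the zone behaves like a stirred tank
#' (dispersion-dominated); above it, like a plug-flow pipe.
#'
#' @param Bo Bodenstein number (> 0).
#' @param critical transition value (default 5).
#' @return `"stirred_tank"` or `"plug_flow"`.
#' @export
classify_regime <- function(Bo, critical = 5) {
  check_number(Bo, "Bo", lower = 0, strict_lower = TRUE)
  if (Bo < critical) "stirred_tank" else "plug_flow"
}

#' Full tracer analysis of an outlet curve
#'
#' Convenience wrapper: moments, voidage, and both Danckwerts dispersion
#' estimates for a module treated as a single equivalent vessel.
#'
#' @param curve a [tracer_curve()].
#' @param t_instrument extra-column (instrument) mean residence time, min.
#'   Measured separately, never estimated from the module run.
#' @param Vm module volume, mL.
#' @param l characteristic length of the equivalent vessel, cm.
#' @return List with the moment results, `voidage`, `Dax_closed`,
#'   `Dax_open` (cm^2/min for minute-based curves; multiply by 1/60 for
#'   cm^2/s) and `bodenstein` numbers for both estimates.
#' @export
tracer_fit <- function(curve, t_instrument, Vm, l) {
  m <- moments(curve)
  eps <- voidage(m$t_mean, t_instrument, curve$flow, Vm)
  tm <- m$t_mean - t_instrument
  v <- l / tm                       # cm/min through the equivalent vessel
  nv <- m$variance / tm^2
  dax_c <- dax_from_variance_closed(min(nv, 1 - 1e-12), v, l)
  dax_o <- dax_from_variance_open(nv, v, l)
  list(moments = m, voidage = eps, Dax_closed = dax_c, Dax_open = dax_o,
       Bo_closed = bodenstein(v, l, dax_c), Bo_open = bodenstein(v, l, dax_o))
}
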