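#' Component of a chromatographic separation system
#'
#' A component is a dissolved species tracked by the simulator: the product,
#' a weak- or strong-binding side component, a non-binding tracer, or the
#' modifier (salt) that controls binding strength.
#'
#' @param id small integer identifier, unique within a [component_system()].
#' @param name character name.
#' @param role one of `"product"`, `"weak_binder"`, `"strong_binder"`,
#'   `"tracer"`, `"modifier"`.
#' @return An object of class `mc_component`.
#' @export
component <- function(id, name, role = c("product", "weak_binder",
                                         "strong_binder", "tracer",
                                         "modifier")) {
  role <- match.arg(role)
  check_number(id, "id")
  if (!is.character(name) || length(name) != 1L)
    stopf("'name' must be a single character string")
  structure(list(id = as.integer(id), name = name, role = role),
            class = "mc_component")
}

#' Component system with feed concentrations
#'
#' Bundles the components of a separation problem with their feed
#' concentrations.  Protein concentrations are in g/L, the modifier (salt)
#' concentration in mol/L.
#'
#' @param components list of [component()] objects.
#' @param feed_concentrations numeric vector, one entry per component
#'   (g/L for proteins/tracers, mol/L for the modifier); must be >= 0.
#' @return An object of class `mc_component_system`.
#' @export
component_system <- function(components, feed_concentrations) {
  if (!length(components))
    stopf("'components' must be a non-empty list")
  ids <- vapply(components, function(x) x$id, integer(1))
  if (anyDuplicated(ids))
    stopf("component ids must be unique; duplicated: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  roles <- vapply(components, function(x) x$role, character(1))
  if (sum(roles == "modifier") > 1L)
    stopf("at most one modifier component is allowed per system")
  if (length(feed_concentrations) != length(components))
    stopf("'feed_concentrations' must have one entry per component")
  if (any(!is.finite(feed_concentrations)) || any(feed_concentrations < 0))
    stopf("feed concentrations must be finite and >= 0")
  names(feed_concentrations) <- vapply(components, function(x) x$name,
                                       character(1))
  structure(list(components = components,
                 feed_concentrations = feed_concentrations),
            class = "mc_component_system")
}

cs_roles <- function(cs) vapply(cs$components, function(x) x$role, character(1))
cs_names <- function(cs) vapply(cs$components, function(x) x$name, character(1))
cs_modifier_index <- function(cs) {
  i <- which(cs_roles(cs) == "modifier")
  if (length(i)) i else NA_integer_
}
cs_binding_indices <- function(cs)
  which(cs_roles(cs) %in% c("product", "weak_binder", "strong_binder"))

#' Geometry of a wrap-around membrane chromatography module
#'
#' Describes the five flow zones of a radial-flow membrane module: the inlet
#' pipe (zone 1), the flow-splitting annular gap (zone 2), the membrane bed
#' itself (zone 3, radial flow), the stream-merging inner cylinder (zone 4)
#' and the outlet pipe (zone 5).  `Vm` is the membrane (bed) volume and also
#' the basis of the CV (column volume) unit.  The total voidage `eps` lumps
#' the hold-up volumes of zones 1/2/4/5 with the internal porosity of the
#' membrane: `eps * Vm = V1 + V2 + V4 + V5 + eps_mem * Vm`, from which the
#' membrane porosity `eps_mem` is derived.
#'
#' @param Vm membrane volume, mL (> 0); equals one CV.
#' @param bed_height membrane bed height (radial flow-path length), mm.
#' @param eps total voidage (0 < eps < 1), the accessible liquid fraction of
#'   the module measured by non-binding tracers.
#' @param zone_volumes numeric length 4: hold-up volumes of zones 1, 2, 4, 5
#'   in mL (the zone-3 volume is `Vm`).
#' @param zone_lengths numeric length 5: flow-path lengths of zones 1..5 in
#'   cm (entry 3 defaults to `bed_height / 10`).
#' @return An object of class `mc_geometry` with derived fields
#'   `eps_mem` (membrane porosity) and per-zone cross sections (cm^2).
#' @export
module_geometry <- function(Vm, bed_height = 8, eps = 0.8,
                            zone_volumes = NULL, zone_lengths = NULL) {
  check_number(Vm, "Vm", lower = 0, strict_lower = TRUE)
  check_number(bed_height, "bed_height", lower = 0, strict_lower = TRUE)
  check_number(eps, "eps", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  ## hold-up defaults scale with the module: 16% of Vm distributed as
  ## 2% / 6% / 6% / 2% over zones 1 / 2 / 4 / 5 (documented assumption for a
  ## laboratory "Nano"-type device whose internal dimensions are unpublished)
  if (is.null(zone_volumes))
    zone_volumes <- Vm * c(0.02, 0.06, 0.06, 0.02)
  if (length(zone_volumes) != 4L || any(!is.finite(zone_volumes)) ||
      any(zone_volumes <= 0))
    stopf("'zone_volumes' must be 4 positive numbers (zones 1, 2, 4, 5, mL)")
  if (is.null(zone_lengths)) {
    ## pipe and annular-gap lengths scale with the cube root of module size
    s <- (Vm / 3)^(1 / 3)
    zone_lengths <- c(5 * s, 2.5 * s, bed_height / 10, 2.5 * s, 5 * s)
  }
  if (length(zone_lengths) != 5L || any(!is.finite(zone_lengths)) ||
      any(zone_lengths <= 0))
    stopf("'zone_lengths' must be 5 positive numbers (cm)")
  holdup <- sum(zone_volumes)
  eps_mem <- (eps * Vm - holdup) / Vm
  if (eps_mem <= 0 || eps_mem >= 1)
    stopf(paste("derived membrane porosity %.3f is outside (0, 1);",
                "total voidage eps = %g is inconsistent with hold-up",
                "volumes summing to %g mL for Vm = %g mL"),
          eps_mem, eps, holdup, Vm)
  vols <- c(zone_volumes[1:2], Vm, zone_volumes[3:4])
  structure(list(Vm = Vm, bed_height = bed_height, eps = eps,
                 eps_mem = eps_mem,
                 zone_volumes = vols,
                 zone_lengths = zone_lengths,
                 zone_areas = vols / zone_lengths),
            class = "mc_geometry")
}

#' @export
print.mc_geometry <- function(x, ...) {
  cat("Membrane module geometry\n")
  cat(sprintf("  Vm (membrane volume / 1 CV): %g mL\n", x$Vm))
  cat(sprintf("  bed height: %g mm, total voidage: %g, membrane porosity: %.3f\n",
              x$bed_height, x$eps, x$eps_mem))
  cat(sprintf("  zone volumes (mL): %s\n",
              paste(signif(x$zone_volumes, 4), collapse = ", ")))
  cat(sprintf("  zone lengths (cm): %s\n",
              paste(signif(x$zone_lengths, 4), collapse = ", ")))
  invisible(x)
}

#' Per-zone axial dispersion coefficients
#'
#' @param Dax numeric length 5, axial dispersion coefficient per zone in
#'   cm^2/s, all > 0.  The defaults are the fitted values for a
#'   laboratory-scale module: 9e-4 cm^2/s for the inlet pipe and annular gap,
#'   5e-3 cm^2/s for the membrane, and 250 cm^2/s for the merging cylinder
#'   and outlet pipe (these two zones behave as stirred tanks).
#' @return An object of class `mc_fluidics`.
#' @export
zone_fluidics <- function(Dax = c(9e-4, 9e-4, 5e-3, 250, 250)) {
  if (length(Dax) != 5L || any(!is.finite(Dax)) || any(Dax <= 0))
    stopf("'Dax' must be 5 positive numbers (cm^2/s, zones 1..5)")
  structure(list(Dax = as.numeric(Dax)), class = "mc_fluidics")
}

#' Operating step of a chromatographic protocol
#'
#' Durations are in CV (column volumes), flows in CV/min; both are resolved
#' against the geometry of the module the step acts on.  The modifier
#' concentration ramps linearly from `modifier_start` to `modifier_end`
#' across the step.
#'
#' @param name step name, unique within a schedule.
#' @param duration_cv step duration in CV (> 0).
#' @param flow_cv flow rate in CV/min (> 0).
#' @param inlet named numeric vector of inlet concentrations (g/L) for
#'   non-modifier components; components not named are fed at 0.
#' @param modifier_start,modifier_end modifier concentration (mol/L) at the
#'   start/end of the step (>= 0); `modifier_end` defaults to
#'   `modifier_start`.
#' @return An object of class `mc_step`.
#' @export
operating_step <- function(name, duration_cv, flow_cv, inlet = numeric(0),
                           modifier_start = 0, modifier_end = modifier_start) {
  if (!is.character(name) || length(name) != 1L)
    stopf("'name' must be a single string")
  check_number(duration_cv, "duration_cv", lower = 0, strict_lower = TRUE)
  check_number(flow_cv, "flow_cv", lower = 0, strict_lower = TRUE)
  check_number(modifier_start, "modifier_start", lower = 0)
  check_number(modifier_end, "modifier_end", lower = 0)
  if (length(inlet) && is.null(names(inlet)))
    stopf("'inlet' must be a named numeric vector")
  structure(list(name = name, duration_cv = duration_cv, flow_cv = flow_cv,
                 inlet = inlet, modifier_start = modifier_start,
                 modifier_end = modifier_end),
            class = "mc_step")
}

#' Ordered sequence of operating steps
#'
#' @param ... [operating_step()] objects (or a single list of them).
#' @return An object of class `mc_schedule`.
#' @export
process_schedule <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1L]], "mc_step"))
    steps <- steps[[1L]]
  if (!length(steps))
    stopf("a schedule needs at least one step")
  if (!all(vapply(steps, inherits, logical(1), "mc_step")))
    stopf("all schedule entries must be operating_step objects")
  nm <- vapply(steps, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stopf("step names must be unique within a schedule; duplicated: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(steps = steps), class = "mc_schedule")
}

#' @export
print.mc_schedule <- function(x, ...) {
  cat("Process schedule:\n")
  for (s in x$steps)
    cat(sprintf("  %-12s %5.2f CV at %4.2f CV/min, modifier %g -> %g M\n",
                s$name, s$duration_cv, s$flow_cv,
                s$modifier_start, s$modifier_end))
  invisible(x)
}

#' Convert a duration in column volumes to a liquid volume
#'
#' @param duration_cv duration/volume in CV (>= 0).
#' @param geometry a [module_geometry()] (defines 1 CV = `Vm` mL).
#' @return Volume in mL.
#' @export
cv_to_volume <- function(duration_cv, geometry) {
  if (!is.numeric(duration_cv) || any(!is.finite(duration_cv)) ||
      any(duration_cv < 0))
    stopf("'duration_cv' must be finite and >= 0")
  if (!inherits(geometry, "mc_geometry"))
    stopf("'geometry' must be a module_geometry object")
  duration_cv * geometry$Vm
}
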