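#' Validate a configuration and build the domain objects
#'
#' Consumes a configuration as a nested list (usually parsed from YAML,
#' see [read_config()]) with sections `geometry`, `fluidics`, `components`,
#' `isotherms`, `schedule`, `process` and `case_study`, checks every
#' invariant, and injects defaults for omitted fields (total voidage 0.8;
#' per-zone dispersion 9e-4, 9e-4, 5e-3, 250, 250 cm^2/s).
#'
#' @param raw nested list.
#' @return List with entries `geometry`, `fluidics`, `system`, `isotherm`,
#'   `schedule`, `case_study` (entries are `NULL` when the section is
#'   absent) and `raw` (the normalized configuration list).
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) stopf("configuration must be a list (parsed YAML)")
  geometry <- NULL
  if (!is.null(raw$geometry)) {
    g <- raw$geometry
    if (is.null(g$Vm)) stopf("geometry: required field 'Vm' (mL) is missing")
    geometry <- module_geometry(
      Vm = g$Vm, bed_height = g$bed_height %||% 8, eps = g$eps %||% 0.8,
      zone_volumes = if (!is.null(g$zone_volumes)) unlist(g$zone_volumes),
      zone_lengths = if (!is.null(g$zone_lengths)) unlist(g$zone_lengths))
  }
  fluidics <- zone_fluidics(unlist(raw$fluidics$Dax %||%
                                     c(9e-4, 9e-4, 5e-3, 250, 250)))
  system <- NULL
  if (!is.null(raw$components)) {
    comps <- lapply(raw$components, function(cc) {
      if (is.null(cc$id) || is.null(cc$name) || is.null(cc$role))
        stopf("components: each entry needs fields id, name, role")
      component(cc$id, cc$name, cc$role)
    })
    feed <- vapply(raw$components, function(cc) cc$feed %||% 0, numeric(1))
    system <- component_system(comps, feed)
  }
  isotherm <- NULL
  if (!is.null(raw$isotherms)) {
    iso <- raw$isotherms
    for (f in c("a1", "a2", "b1", "b2"))
      if (is.null(iso[[f]])) stopf("isotherms: required field '%s' missing", f)
    isotherm <- isotherm_params(
      unlist(iso$a1), unlist(iso$a2), unlist(iso$b1), unlist(iso$b2),
      L1 = iso$L1 %||% 0, kla = iso$kla %||% 6,
      cmod_range = unlist(iso$cmod_range %||% c(0, 1)),
      component_names = if (!is.null(system))
        cs_names(system)[cs_binding_indices(system)])
  }
  schedule <- NULL
  if (!is.null(raw$schedule)) {
    steps <- lapply(raw$schedule, function(s) {
      if (is.null(s$name) || is.null(s$duration_cv) || is.null(s$flow_cv))
        stopf("schedule: each step needs name, duration_cv, flow_cv")
      operating_step(s$name, s$duration_cv, s$flow_cv,
                     inlet = unlist(s$inlet) %||% numeric(0),
                     modifier_start = s$modifier_start %||% 0,
                     modifier_end = s$modifier_end %||%
                       (s$modifier_start %||% 0))
    })
    schedule <- process_schedule(steps)
  }
  case_study <- NULL
  if (!is.null(raw$case_study)) {
    cs <- raw$case_study
    for (f in c("fermenter_volume", "titer", "module_volume", "batch_runs"))
      if (is.null(cs[[f]])) stopf("case_study: required field '%s' missing", f)
    case_study <- case_study_spec(
      fermenter_volume = cs$fermenter_volume, titer = cs$titer,
      batches_per_year = cs$batches_per_year %||% 40,
      module_volume = cs$module_volume, batch_runs = cs$batch_runs,
      n_modules_sequential = cs$n_modules_sequential %||% 4,
      load_flow_batch = cs$load_flow_batch %||% 5,
      load_flow_seq = cs$load_flow_seq %||% 3,
      elution_cv = cs$elution_cv %||% 15,
      elution_flow = cs$elution_flow %||% 5,
      capacity_gain_factor = cs$capacity_gain_factor %||% 1.71)
  }
  normalized <- raw
  normalized$fluidics <- list(Dax = fluidics$Dax)
  if (!is.null(geometry))
    normalized$geometry <- list(Vm = geometry$Vm,
                                bed_height = geometry$bed_height,
                                eps = geometry$eps,
                                zone_volumes =
                                  geometry$zone_volumes[c(1, 2, 4, 5)],
                                zone_lengths = geometry$zone_lengths)
  list(geometry = geometry, fluidics = fluidics, system = system,
       isotherm = isotherm, schedule = schedule, case_study = case_study,
       raw = normalized)
}

#' Read and validate a YAML configuration file
#'
#' @param path YAML file with the sections accepted by [validate_config()].
#' @return See [validate_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validate_config(yaml::read_yaml(path))
}

#' Serialize a validated configuration back to YAML
#'
#' `read_config(write_config(cfg, f))` reproduces an equivalent
#' configuration (round trip).
#'
#' @param config result of [validate_config()] / [read_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Export fitted isotherm parameters as a config-compatible fragment
#'
#' @param fit an `mc_isotherm_fit` (or [isotherm_params()]).
#' @param path optional YAML output path.
#' @return The fragment list (section `isotherms`), invisibly if written.
#' @export
isotherm_config_fragment <- function(fit, path = NULL) {
  p <- if (inherits(fit, "mc_isotherm_fit")) fit$params else fit
  frag <- list(isotherms = list(a1 = p$a1, a2 = p$a2, b1 = p$b1, b2 = p$b2,
                                L1 = p$L1, kla = p$kla,
                                cmod_range = p$cmod_range))
  if (!is.null(path)) {
    yaml::write_yaml(frag, path)
    return(invisible(frag))
  }
  frag
}
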