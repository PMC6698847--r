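#' Bundle a module's physics into one configuration object
#'
#' @param geometry a [module_geometry()].
#' @param fluidics a [zone_fluidics()].
#' @param isotherm an [isotherm_params()].
#' @param resolution cells per zone used when this module is simulated.
#' @return An object of class `mc_module`.
#' @export
module_config <- function(geometry, fluidics = zone_fluidics(),
                          isotherm = NULL,
                          resolution = c(8L, 8L, 12L, 8L, 8L)) {
  structure(list(geometry = geometry, fluidics = fluidics,
                 isotherm = isotherm, resolution = resolution),
            class = "mc_module")
}

sim_mod <- function(module, system, schedule, ...) {
  simulate_module(module$geometry, module$fluidics, system, schedule,
                  isotherm = module$isotherm,
                  resolution = module$resolution, ...)
}

## schedule for a plain loading phase
load_schedule <- function(duration_cv, flow_cv, feed, modifier) {
  roles <- cs_roles(feed)
  inlet <- feed$feed_concentrations[roles != "modifier"]
  process_schedule(operating_step("load", duration_cv, flow_cv,
                                  inlet = inlet,
                                  modifier_start = modifier))
}

#' Run one batch load-and-elute cycle on a single module
#'
#' Loads the module with feed at the loading flow, then runs the elution
#' protocol, and reports the loaded and eluted masses and the capacity
#' utilization.  If a pressure model is supplied the loading pressure is
#' checked before any simulation starts.
#'
#' @param module a [module_config()].
#' @param feed a [component_system()].
#' @param load_cv feed volume, CV (>= 0; 0 skips loading).
#' @param elution_protocol a [process_schedule()]
#'   (wash/gradient/regeneration/equilibration).
#' @param load_flow_cv loading flow, CV/min.
#' @param load_modifier modifier concentration during loading, mol/L.
#' @param pressure optional [pressure_model()]; loading must respect it.
#' @param dt_report,rtol,atol passed to [simulate_module()].
#' @return An object of class `mc_cycle` with loaded/eluted masses (mg),
#'   `utilization` (g product per L membrane), the loading and elution
#'   simulations, and mass-balance diagnostics.
#' @export
run_batch_cycle <- function(module, feed, load_cv, elution_protocol,
                            load_flow_cv = 5, load_modifier = 0.02,
                            pressure = NULL, dt_report = 1 / 60,
                            rtol = 1e-6, atol = 1e-9) {
  if (!is.null(pressure)) {
    pr <- pressure_drop(load_flow_cv, 1, pressure)
    if (!pr$within_limit)
      stopf("loading pressure %.2f bar exceeds the %.1f bar limit",
            pr$pressure, pr$limit)
  }
  state <- NULL
  loaded <- numeric(0)
  load_sim <- NULL
  if (load_cv > 0) {
    load_sim <- sim_mod(module, feed,
                        load_schedule(load_cv, load_flow_cv, feed,
                                      load_modifier),
                        dt_report = dt_report, rtol = rtol, atol = atol)
    state <- load_sim$final_state
    loaded <- load_sim$bound_mass
  }
  elu_sim <- sim_mod(module, feed, elution_protocol, initial_state = state,
                     dt_report = dt_report, rtol = rtol, atol = atol)
  eluted <- elu_sim$mass_balance$eluted_mg
  names(eluted) <- elu_sim$mass_balance$component
  prod_name <- cs_names(feed)[cs_roles(feed) == "product"][1]
  util <- if (length(loaded)) loaded[prod_name] / module$geometry$Vm else 0
  structure(list(loaded_mg = loaded, eluted_mg = eluted,
                 utilization = unname(util),
                 load_sim = load_sim, elution_sim = elu_sim,
                 chromatogram = elu_sim$chromatogram),
            class = "mc_cycle")
}

#' Sequential (counter-current loading) process configuration
#'
#' @param module a [module_config()]; all modules in the train are
#'   identical.
#' @param n_modules modules connected in series during loading (>= 1).
#' @param load_flow_cv loading flow, CV/min.
#' @param elution_protocol a [process_schedule()] run on the decoupled
#'   module.
#' @param breakthrough_threshold loading stops when the product
#'   concentration at the last module's outlet reaches this fraction of the
#'   feed concentration (0 < threshold < 1; default 1 percent).
#' @param load_modifier modifier during loading, mol/L.
#' @param pressure optional [pressure_model()] checked for the full train.
#' @param strict error (instead of warn) when the batch-phase duration
#'   exceeds the loading duration of the chain.
#' @return An object of class `mc_sequential_config`.
#' @export
sequential_config <- function(module, n_modules, load_flow_cv = 3,
                              elution_protocol,
                              breakthrough_threshold = 0.01,
                              load_modifier = 0.02, pressure = NULL,
                              strict = FALSE) {
  check_number(n_modules, "n_modules", lower = 1)
  check_number(breakthrough_threshold, "breakthrough_threshold",
               lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(load_flow_cv, "load_flow_cv", lower = 0, strict_lower = TRUE)
  structure(list(module = module, n_modules = as.integer(n_modules),
                 load_flow_cv = load_flow_cv,
                 elution_protocol = elution_protocol,
                 breakthrough_threshold = breakthrough_threshold,
                 load_modifier = load_modifier, pressure = pressure,
                 strict = strict),
            class = "mc_sequential_config")
}

## simulate the loading phase of a chain of modules in series.
## states: list of initial states (NULL = clean).  Returns per-module
## simulations over [0, T], the breakthrough time of the last module
## (NA if not reached), and per-module outlet interpolators.
chain_load <- function(config, feed, states, T_cv) {
  module <- config$module
  flow_cv <- config$load_flow_cv
  nmod <- config$n_modules
  roles <- cs_roles(feed)
  nms <- cs_names(feed)
  prod <- nms[roles == "product"][1]
  sims <- vector("list", nmod)
  inlet_fun <- NULL
  sched <- load_schedule(T_cv, flow_cv, feed, config$load_modifier)
  for (k in seq_len(nmod)) {
    sims[[k]] <- sim_mod(module, feed, sched,
                         initial_state = states[[k]],
                         inlet_fun = inlet_fun,
                         dt_report = max(T_cv / flow_cv / 300, 1e-3))
    ch <- sims[[k]]$chromatogram
    funs <- lapply(nms, function(nm) {
      y <- if (nm %in% colnames(ch$conc)) ch$conc[, nm] else ch$modifier
      stats::approxfun(ch$time, y, rule = 2)
    })
    inlet_fun <- local({
      fs <- funs
      function(t) vapply(fs, function(f) f(t), numeric(1))
    })
  }
  last <- sims[[nmod]]$chromatogram
  thr <- config$breakthrough_threshold * feed$feed_concentrations[prod]
  t_b <- breakthrough_time(last, prod, thr)
  list(sims = sims, t_b = t_b)
}

## bound mass (mg) of the named components on a module at time t,
## interpolated from the stored state trajectory of its loading simulation
bound_mass_at <- function(sim, t, comps) {
  tr <- sim$bound_trace
  vapply(comps, function(nm)
    stats::approx(tr$time, tr[[nm]], xout = t, rule = 2)$y, numeric(1))
}

#' Run a sequential counter-current capture process
#'
#' Per cycle: the modules are connected in series and loaded until the
#' product breakthrough at the last module's outlet reaches the configured
#' threshold; the first module is then decoupled and eluted, and the chain
#' is rotated (the former second module becomes the head).
#'
#' @param config a [sequential_config()].
#' @param feed a [component_system()].
#' @param n_cycles number of cycles to run.
#' @return List of `mc_cycle` objects (one per cycle), each with the loaded
#'   product mass on the head module, the breakthrough (switch) time, the
#'   eluted pool, and capacity utilization.
#' @export
run_sequential <- function(config, feed, n_cycles = 1) {
  if (!is.null(config$pressure)) {
    pr <- pressure_drop(config$load_flow_cv, config$n_modules,
                        config$pressure)
    if (!pr$within_limit)
      stopf("train pressure %.2f bar exceeds the %.1f bar limit",
            pr$pressure, pr$limit)
  }
  module <- config$module
  roles <- cs_roles(feed)
  prod <- cs_names(feed)[roles == "product"][1]
  ## initial loading-duration guess from the static capacity
  qstar <- q_equilibrium(feed$feed_concentrations[cs_binding_indices(feed)],
                         config$load_modifier, module$isotherm)
  cap_cv <- qstar[prod] / feed$feed_concentrations[prod]
  states <- vector("list", config$n_modules)
  protocol_min <- sum(vapply(config$elution_protocol$steps,
                             function(s) s$duration_cv / s$flow_cv,
                             numeric(1)))
  cycles <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    T_cv <- (cap_cv * config$n_modules + 2) * 1.3
    res <- NULL
    for (try in 1:4) {
      res <- chain_load(config, feed, states, T_cv)
      if (!is.na(res$t_b)) break
      T_cv <- T_cv * 1.6
    }
    if (is.na(res$t_b))
      stopf("no breakthrough within %.1f CV of loading; threshold too high?",
            T_cv)
    t_b <- res$t_b
    if (protocol_min > t_b) {
      msg <- sprintf(paste("batch phase (%.2f min) is longer than the",
                           "loading phase (%.2f min): the schedule is not",
                           "feasible without extra modules"),
                     protocol_min, t_b)
      if (config$strict) stopf("%s", msg) else warning(msg, call. = FALSE)
    }
    ## re-simulate the chain up to the switch time for the module states
    cut_cv <- t_b * config$load_flow_cv
    res_b <- chain_load(config, feed, states, cut_cv)
    loaded <- res_b$sims[[1L]]$bound_mass
    ## elute the head module
    elu <- sim_mod(module, feed, config$elution_protocol,
                   initial_state = res_b$sims[[1L]]$final_state)
    eluted <- elu$mass_balance$eluted_mg
    names(eluted) <- elu$mass_balance$component
    cycles[[cy]] <- structure(
      list(loaded_mg = loaded, eluted_mg = eluted,
           utilization = unname(loaded[prod] / module$geometry$Vm),
           switch_time_min = t_b, load_cv = cut_cv,
           breakthrough_chromatogram =
             res_b$sims[[config$n_modules]]$chromatogram,
           chromatogram = elu$chromatogram),
      class = "mc_cycle")
    ## rotate: head is regenerated and joins the tail
    states <- c(lapply(res_b$sims[-1L], function(s) s$final_state),
                list(NULL))
  }
  cycles
}

#' Loading-gain study for sequential chains
#'
#' Runs the loading phase only for chains of `n` modules and reports the
#' protein mass loaded on the first module at the breakthrough of the last
#' one, and its gain relative to a single module.  "Loading" counts total
#' bound protein (product plus side components), the quantity a UV-based
#' loading measurement sees; the product share is reported separately.
#'
#' @param config a [sequential_config()] (its `n_modules` is overridden).
#' @param feed a [component_system()].
#' @param n_range integer vector of chain lengths (within 1..10).
#' @return Data frame with `n_modules`, `loaded_mg` (total protein),
#'   `product_mg`, `gain_percent`.
#' @export
loading_gain_study <- function(config, feed, n_range = 1:4) {
  if (any(n_range < 1L) || any(n_range > 10L))
    stopf("'n_range' must lie within 1..10")
  roles <- cs_roles(feed)
  prod <- cs_names(feed)[roles == "product"][1]
  binders <- cs_names(feed)[cs_binding_indices(feed)]
  qstar <- q_equilibrium(feed$feed_concentrations[cs_binding_indices(feed)],
                         config$load_modifier, config$module$isotherm)
  cap_cv <- qstar[prod] / feed$feed_concentrations[prod]
  out <- lapply(n_range, function(n) {
    cfg <- config
    cfg$n_modules <- as.integer(n)
    T_cv <- (cap_cv * n + 2) * 1.3
    res <- NULL
    for (try in 1:4) {
      res <- chain_load(cfg, feed, vector("list", n), T_cv)
      if (!is.na(res$t_b)) break
      T_cv <- T_cv * 1.6
    }
    if (is.na(res$t_b)) stopf("no breakthrough for n = %d", n)
    bm <- bound_mass_at(res$sims[[1L]], res$t_b, binders)
    c(total = sum(bm), product = unname(bm[prod]))
  })
  loaded <- vapply(out, `[[`, numeric(1), "total")
  ref <- loaded[match(1L, n_range)]
  if (is.na(ref)) ref <- loaded[1L]
  data.frame(n_modules = n_range, loaded_mg = loaded,
             product_mg = vapply(out, `[[`, numeric(1), "product"),
             gain_percent = 100 * (loaded / ref - 1))
}
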