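#' Linear pressure-drop model for a module train
#'
#' Backpressure grows linearly with flow rate and with the number of modules
#' in series; instruments and piping add a constant offset.
#'
#' @param per_module_coefficient bar per (CV/min) per module (>= 0).
#' @param instrument_offset constant instrument backpressure, bar (>= 0).
#' @param limit maximum admissible pressure in the first module, bar (> 0).
#' @return An object of class `mc_pressure_model`.
#' @export
pressure_model <- function(per_module_coefficient = 0.2,
                           instrument_offset = 1.1, limit = 4) {
  check_number(per_module_coefficient, "per_module_coefficient", lower = 0)
  check_number(instrument_offset, "instrument_offset", lower = 0)
  check_number(limit, "limit", lower = 0, strict_lower = TRUE)
  structure(list(per_module_coefficient = per_module_coefficient,
                 instrument_offset = instrument_offset, limit = limit),
            class = "mc_pressure_model")
}

#' Total backpressure of a module train
#'
#' `n_modules * coefficient * flow + instrument_offset`, compared against
#' the model's pressure limit.
#'
#' @param flow loading flow, CV/min (> 0 allowed; 0 gives offset only).
#' @param n_modules number of modules in series (>= 1).
#' @param model a [pressure_model()].
#' @param include_offset include the instrument offset? (`FALSE` isolates
#'   the module contribution.)
#' @return List with `pressure` (bar), `limit`, and `within_limit`.
#' @export
pressure_drop <- function(flow, n_modules, model = pressure_model(),
                          include_offset = TRUE) {
  check_number(flow, "flow", lower = 0)
  check_number(n_modules, "n_modules", lower = 1)
  p <- n_modules * model$per_module_coefficient * flow +
    if (include_offset) model$instrument_offset else 0
  list(pressure = p, limit = model$limit, within_limit = p <= model$limit)
}

#' Case-study specification for batch-vs-sequential capture
#'
#' Describes a fed-batch upstream (fermenter volume, titer, batches per
#' year) and the chromatography train that processes each harvest, for
#' both the batch reference and the sequential counter-current process.
#'
#' @param fermenter_volume harvest volume, L.
#' @param titer product concentration in the harvest, g/L.
#' @param batches_per_year upstream batches per year.
#' @param module_volume membrane volume of one module, L (batch process).
#' @param module_volume_seq module volume used by the sequential train, L
#'   (defaults to `module_volume`; continuous operation admits much smaller
#'   modules).
#' @param batch_runs number of batch runs needed per harvest.
#' @param n_modules_sequential modules in series during sequential loading.
#' @param load_flow_batch,load_flow_seq loading flow, CV/min.
#' @param elution_cv total wash/gradient/regeneration/equilibration volume,
#'   CV (e.g. 3 + 6 + 3 + 3 = 15).
#' @param elution_flow protocol flow, CV/min.
#' @param capacity_gain_factor sequential capacity relative to batch
#'   (>= 1); e.g. 1.71 for a 71 percent gain with four modules.
#' @param harvest_interval days between harvests (batch-to-batch
#'   productivity basis); default `365 / batches_per_year`.
#' @return An object of class `mc_case_spec`.
#' @export
case_study_spec <- function(fermenter_volume, titer, batches_per_year = 40,
                            module_volume, batch_runs,
                            module_volume_seq = module_volume,
                            n_modules_sequential = 4,
                            load_flow_batch = 5, load_flow_seq = 3,
                            elution_cv = 15, elution_flow = 5,
                            capacity_gain_factor = 1.71,
                            harvest_interval = 365 / batches_per_year) {
  for (nm in c("fermenter_volume", "titer", "batches_per_year",
               "module_volume", "module_volume_seq", "batch_runs",
               "n_modules_sequential",
               "load_flow_batch", "load_flow_seq", "elution_cv",
               "elution_flow", "harvest_interval"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(capacity_gain_factor, "capacity_gain_factor", lower = 1)
  structure(list(fermenter_volume = fermenter_volume, titer = titer,
                 batches_per_year = batches_per_year,
                 module_volume = module_volume,
                 module_volume_seq = module_volume_seq,
                 batch_runs = batch_runs,
                 n_modules_sequential = n_modules_sequential,
                 load_flow_batch = load_flow_batch,
                 load_flow_seq = load_flow_seq,
                 elution_cv = elution_cv, elution_flow = elution_flow,
                 capacity_gain_factor = capacity_gain_factor,
                 harvest_interval = harvest_interval),
            class = "mc_case_spec")
}

#' Batch capacity utilization implied by a case-study sizing
#'
#' Mass processed per run divided by module volume:
#' `fermenter_volume * titer / (batch_runs * module_volume)`, in g per L of
#' membrane.
#'
#' @param spec a [case_study_spec()].
#' @return Capacity in g/L-membrane.
#' @export
batch_capacity <- function(spec) {
  spec$fermenter_volume * spec$titer / (spec$batch_runs * spec$module_volume)
}

#' Duration of one load-and-elute cycle
#'
#' Loading time (the feed volume needed to deposit `capacity` grams per
#' litre of membrane, in CV, divided by the load flow) plus the elution
#' protocol time.  The module volume cancels: `capacity / titer` is the
#' loading duration in CV.
#'
#' @param capacity capacity utilization, g/L-membrane.
#' @param titer feed concentration, g/L.
#' @param load_flow loading flow, CV/min.
#' @param elution_cv protocol volume, CV.
#' @param elution_flow protocol flow, CV/min.
#' @return Cycle time in minutes.
#' @export
cycle_time <- function(capacity, titer, load_flow, elution_cv, elution_flow) {
  (capacity / titer) / load_flow + elution_cv / elution_flow
}

#' Productivity per run/cycle
#'
#' `capacity * 1440 / cycle_time`: grams of product per litre of membrane
#' per day, on the basis of the duration of one cycle.
#'
#' @param capacity capacity utilization, g/L-membrane.
#' @param cycle_time_min cycle duration, min (> 0).
#' @return Productivity, g/L/day.
#' @export
productivity_per_cycle <- function(capacity, cycle_time_min) {
  check_number(cycle_time_min, "cycle_time_min", lower = 0,
               strict_lower = TRUE)
  capacity * 1440 / cycle_time_min
}

#' Eluent consumption per gram of product
#'
#' Total pumped liquid (feed plus the full protocol buffer volume, in CV)
#' per gram of product: `(capacity / titer + elution_cv) / capacity`.  The
#' module volume cancels.  Set `buffer_only = TRUE` to count protocol
#' buffer only (excluding the feed itself).
#'
#' @param capacity capacity utilization, g/L-membrane (> 0).
#' @param titer feed concentration, g/L.
#' @param elution_cv protocol volume, CV.
#' @param buffer_only count only protocol buffer, not the feed.
#' @return Consumption in L of liquid per g of product.
#' @export
eluent_consumption <- function(capacity, titer, elution_cv,
                               buffer_only = FALSE) {
  check_number(capacity, "capacity", lower = 0, strict_lower = TRUE)
  feed_cv <- if (buffer_only) 0 else capacity / titer
  (feed_cv + elution_cv) / capacity
}

#' Size the sequential process from the batch sizing and the capacity gain
#'
#' The total membrane volume shrinks by the capacity gain factor; the cycle
#' count follows from the (unrounded) total volume and the membrane volume
#' loaded per cycle.  Total volume is reported rounded to the nearest litre
#' (nearest 0.1 L below 10 L).
#'
#' @param spec a [case_study_spec()].
#' @return List with `total_membrane_volume` (L, rounded),
#'   `total_membrane_volume_raw` (L), and `n_cycles`.
#' @export
size_sequential <- function(spec) {
  batch_total <- spec$batch_runs * spec$module_volume
  raw <- batch_total / spec$capacity_gain_factor
  rounded <- if (raw < 10) round(raw, 1) else round(raw)
  n_cycles <- round(raw / (spec$n_modules_sequential *
                             spec$module_volume_seq))
  list(total_membrane_volume = rounded, total_membrane_volume_raw = raw,
       n_cycles = n_cycles)
}

#' Total batch runtime for one harvest
#'
#' `batch_runs * cycle_time / 60` hours, with the batch loading time taken
#' from the per-run feed volume.
#'
#' @param spec a [case_study_spec()].
#' @return Runtime in hours.
#' @export
batch_runtime <- function(spec) {
  cap <- batch_capacity(spec)
  ct <- cycle_time(cap, spec$titer, spec$load_flow_batch,
                   spec$elution_cv, spec$elution_flow)
  spec$batch_runs * ct / 60
}

#' Performance report for one operating mode
#'
#' Assembles capacity, sizing, runtime, productivities, eluent consumption
#' and the pressure check for either the batch or the sequential variant of
#' a case study.
#'
#' @param spec a [case_study_spec()].
#' @param mode `"batch"` or `"sequential"`.
#' @param pressure a [pressure_model()].
#' @return An object of class `mc_performance_report`.
#' @export
performance_report <- function(spec, mode = c("batch", "sequential"),
                               pressure = pressure_model()) {
  mode <- match.arg(mode)
  cap_b <- batch_capacity(spec)
  if (mode == "batch") {
    capacity <- cap_b
    total_volume <- spec$batch_runs * spec$module_volume
    runs <- spec$batch_runs
    load_flow <- spec$load_flow_batch
    n_mod <- 1
    runtime_h <- batch_runtime(spec)
  } else {
    capacity <- cap_b * spec$capacity_gain_factor
    sz <- size_sequential(spec)
    total_volume <- sz$total_membrane_volume
    runs <- sz$n_cycles
    load_flow <- spec$load_flow_seq
    n_mod <- spec$n_modules_sequential
    ct <- cycle_time(capacity, spec$titer, load_flow,
                     spec$elution_cv, spec$elution_flow)
    ## non-overlapped upper bound: every module of every cycle in sequence
    runtime_h <- runs * n_mod * ct / 60
  }
  ct <- cycle_time(capacity, spec$titer, load_flow,
                   spec$elution_cv, spec$elution_flow)
  pr <- pressure_drop(load_flow, n_mod, pressure)
  structure(list(
    mode = mode,
    capacity = capacity,
    total_membrane_volume = total_volume,
    runs_or_cycles = runs,
    cycle_time_min = ct,
    runtime_h = runtime_h,
    productivity_cycle = productivity_per_cycle(capacity, ct),
    productivity_batch_to_batch = capacity / spec$harvest_interval,
    eluent_consumption = eluent_consumption(capacity, spec$titer,
                                            spec$elution_cv),
    pressure_bar = pr$pressure, pressure_limit = pr$limit,
    within_pressure_limit = pr$within_limit,
    spec = spec), class = "mc_performance_report")
}

#' @export
print.mc_performance_report <- function(x, ...) {
  cat(sprintf("Performance report (%s):\n", x$mode))
  cat(sprintf("  capacity:                %8.3f g/L membrane\n", x$capacity))
  cat(sprintf("  total membrane volume:   %8.3g L\n", x$total_membrane_volume))
  cat(sprintf("  runs/cycles:             %8d\n", x$runs_or_cycles))
  cat(sprintf("  runtime:                 %8.2f h\n", x$runtime_h))
  cat(sprintf("  productivity (cycle):    %8.0f g/L/day\n",
              x$productivity_cycle))
  cat(sprintf("  productivity (b2b):      %8.2f g/L/day\n",
              x$productivity_batch_to_batch))
  cat(sprintf("  eluent consumption:      %8.2f L/g\n",
              x$eluent_consumption))
  cat(sprintf("  pressure:                %8.2f bar (limit %.1f, %s)\n",
              x$pressure_bar, x$pressure_limit,
              if (x$within_pressure_limit) "ok" else "EXCEEDED"))
  invisible(x)
}

#' Compare a sequential report against a batch report
#'
#' Percentage changes of the sequential process relative to the batch
#' process.
#'
#' @param batch,sequential [performance_report()] objects.
#' @return List of deltas in percent: `capacity`, `productivity`,
#'   `eluent`, `runtime`.
#' @export
compare_performance <- function(batch, sequential) {
  pct <- function(new, old) 100 * (new / old - 1)
  list(capacity = pct(sequential$capacity, batch$capacity),
       productivity = pct(sequential$productivity_cycle,
                          batch$productivity_cycle),
       eluent = pct(sequential$eluent_consumption,
                    batch$eluent_consumption),
       runtime = pct(sequential$runtime_h, batch$runtime_h))
}

#' Run a full batch-vs-sequential case study
#'
#' @param spec a [case_study_spec()].
#' @param pressure a [pressure_model()].
#' @return An object of class `mc_case_study`: the two reports plus their
#'   comparison.
#' @export
run_case_study <- function(spec, pressure = pressure_model()) {
  b <- performance_report(spec, "batch", pressure)
  s <- performance_report(spec, "sequential", pressure)
  structure(list(batch = b, sequential = s,
                 deltas = compare_performance(b, s)),
            class = "mc_case_study")
}

#' @export
print.mc_case_study <- function(x, ...) {
  print(x$batch); print(x$sequential)
  cat(sprintf(paste0("Sequential vs batch: %+.1f%% capacity, ",
                     "%+.1f%% productivity, %+.1f%% eluent\n"),
              x$deltas$capacity, x$deltas$productivity, x$deltas$eluent))
  invisible(x)
}

#' @export
as.data.frame.mc_case_study <- function(x, ...) {
  f <- function(r) c(r$total_membrane_volume,
                     if (r$mode == "batch") r$spec$module_volume
                     else r$spec$module_volume_seq,
                     if (r$mode == "batch") 1 else
                       r$spec$n_modules_sequential,
                     r$runs_or_cycles, round(r$runtime_h, 2),
                     round(r$productivity_cycle),
                     round(r$productivity_batch_to_batch, 2),
                     round(r$eluent_consumption, 2))
  out <- data.frame(quantity = c("total_membrane_volume_L",
                                 "module_size_L", "modules_per_cycle",
                                 "runs_or_cycles", "runtime_h",
                                 "productivity_cycle_g_L_day",
                                 "productivity_batch_to_batch_g_L_day",
                                 "eluent_consumption_L_g"),
                    batch = f(x$batch), sequential = f(x$sequential))
  out
}
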