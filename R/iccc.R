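#' Integrated counter-current chromatography (iCCC) configuration
#'
#' Couples an ion-exchange and a hydrophobic-interaction module into a
#' cyclic two-column process.  Each elution chromatogram is divided by
#' three cut points (in CV of elution volume) into a leading waste segment
#' and three fractions; the routing map sends every fraction to exactly one
#' destination.  The default routing follows the classic scheme: the IEX
#' front (sharp, low-salt side) is recycled onto the IEX column, the IEX
#' middle and tail transfer to the HIC column; the HIC front is recycled
#' onto HIC, the HIC middle is the product, and the HIC tail goes back to
#' IEX.
#'
#' @param iex,hic [module_config()] objects.  Their isotherms must show
#'   opposing modifier behavior (IEX binds at low salt, HIC at high salt).
#' @param iex_protocol,hic_protocol elution [process_schedule()]s.
#' @param load_cv fresh feed volume loaded onto IEX per cycle, CV.
#' @param load_flow_cv loading flow, CV/min.
#' @param iex_cuts,hic_cuts strictly increasing cut points, CV of elution
#'   volume (3 each).
#' @param routing named list mapping fraction names `iex_f1`, `iex_f2`,
#'   `iex_f3`, `hic_f1`, `hic_f2`, `hic_f3` to destinations among
#'   `"iex"`, `"hic"`, `"product"`, `"waste"`.
#' @param iex_load_modifier,hic_load_modifier modifier during loading,
#'   mol/L.
#' @param max_cycles maximum number of cycles.
#' @param steady_state_tolerance relative per-fraction change between
#'   consecutive cycles below which the process counts as cyclically
#'   steady.
#' @return An object of class `mc_iccc_config`.
#' @export
iccc_config <- function(iex, hic, iex_protocol, hic_protocol,
                        load_cv = 2, load_flow_cv = 1,
                        iex_cuts, hic_cuts,
                        routing = list(iex_f1 = "iex", iex_f2 = "hic",
                                       iex_f3 = "hic", hic_f1 = "hic",
                                       hic_f2 = "product", hic_f3 = "iex"),
                        iex_load_modifier = 0.02, hic_load_modifier = 1,
                        max_cycles = 6, steady_state_tolerance = 0.03) {
  for (cuts in list(iex_cuts, hic_cuts))
    if (length(cuts) != 3L || any(diff(cuts) <= 0))
      stopf("cut points must be 3 strictly increasing CV values")
  needed <- c("iex_f1", "iex_f2", "iex_f3", "hic_f1", "hic_f2", "hic_f3")
  if (!setequal(names(routing), needed))
    stopf("routing must map exactly the fractions %s",
          paste(needed, collapse = ", "))
  dest <- unlist(routing)
  if (!all(dest %in% c("iex", "hic", "product", "waste")))
    stopf("routing destinations must be iex, hic, product or waste")
  structure(list(iex = iex, hic = hic, iex_protocol = iex_protocol,
                 hic_protocol = hic_protocol, load_cv = load_cv,
                 load_flow_cv = load_flow_cv, iex_cuts = iex_cuts,
                 hic_cuts = hic_cuts, routing = routing,
                 iex_load_modifier = iex_load_modifier,
                 hic_load_modifier = hic_load_modifier,
                 max_cycles = as.integer(max_cycles),
                 steady_state_tolerance = steady_state_tolerance),
            class = "mc_iccc_config")
}

## an empty pool: zero volume, zero mass
empty_pool <- function(comp_names)
  list(volume = 0, mass = stats::setNames(numeric(length(comp_names)),
                                          comp_names),
       modifier = 0)

add_pool <- function(a, b) {
  v <- a$volume + b$volume
  list(volume = v, mass = a$mass + b$mass,
       modifier = if (v > 0)
         (a$modifier * a$volume + b$modifier * b$volume) / v else 0)
}

## cut an elution chromatogram into waste + 3 fractions.  Cut points are
## snapped to the reporting grid so the four windows partition the eluate
## exactly.
fractionate <- function(chrom, cuts_cv, Vm) {
  vol <- cumtrapz(chrom$time, chrom$flow)
  cut_t <- vapply(cuts_cv * Vm, function(v)
    chrom$time[which.min(abs(vol - v))], numeric(1))
  bounds <- c(chrom$time[1L], cut_t, chrom$time[length(chrom$time)])
  lapply(seq_len(4L), function(k) {
    w <- pool_window(chrom, bounds[k], bounds[k + 1L])
    sel <- chrom$time >= bounds[k] & chrom$time <= bounds[k + 1L]
    mod <- if (w$volume > 0)
      trapz(chrom$time[sel], chrom$flow[sel] * chrom$modifier[sel]) /
        w$volume else 0
    list(volume = w$volume, mass = w$mass, modifier = mod)
  })
}

## load schedule for one iCCC column: recycled pool first, then fresh feed
iccc_load_schedule <- function(pools, feed_pool, flow_cv, Vm, modifier) {
  steps <- list()
  for (nm in names(pools)) {
    p <- pools[[nm]]
    if (p$volume <= 1e-9) next
    conc <- p$mass / p$volume
    steps[[length(steps) + 1L]] <-
      operating_step(paste0("load_", nm), p$volume / Vm, flow_cv,
                     inlet = conc, modifier_start = modifier)
  }
  if (!is.null(feed_pool) && feed_pool$volume > 1e-9)
    steps[[length(steps) + 1L]] <-
      operating_step("load_feed", feed_pool$volume / Vm, flow_cv,
                     inlet = feed_pool$mass / feed_pool$volume,
                     modifier_start = modifier)
  if (!length(steps)) return(NULL)
  process_schedule(steps)
}

#' Run an integrated counter-current (iCCC) process
#'
#' Per cycle: the IEX module is loaded with its recycle pool plus fresh
#' feed and eluted; the chromatogram is cut into fractions and routed; the
#' HIC module is loaded with its recycle pool plus the transferred IEX
#' fractions and eluted; its fractions are routed (product, recycles).
#' Recycled fractions are stored as volume-weighted pools and prepended to
#' the next cycle's load.  The run iterates to `max_cycles` or until a
#' cyclic steady state is detected; accumulation (the failure mode of
#' tailing-dominated modules, where recycled product piles up on the IEX
#' column) is flagged but does not stop the run.
#'
#' @param config an [iccc_config()].
#' @param feed a [component_system()] (loaded onto IEX each cycle).
#' @return An object of class `mc_iccc_result`: a list of per-cycle
#'   results (fraction masses in mg, product pool, recycle pools,
#'   conservation checks) plus flags `accumulation_detected` and
#'   `steady_state` (with the cycle index).
#' @export
run_iccc <- function(config, feed) {
  roles <- cs_roles(feed)
  nms <- cs_names(feed)
  prod <- nms[roles == "product"][1]
  protein <- nms[roles != "modifier"]
  feed_conc <- feed$feed_concentrations[protein]
  Vm_iex <- config$iex$geometry$Vm
  Vm_hic <- config$hic$geometry$Vm
  iex_pool <- empty_pool(protein)
  hic_pool <- empty_pool(protein)
  ## static capacity of the IEX column for the overload flag
  q_iex <- q_equilibrium(feed$feed_concentrations[cs_binding_indices(feed)],
                         config$iex_load_modifier, config$iex$isotherm)
  iex_capacity_mg <- q_iex[prod] * Vm_iex
  cycles <- list()
  for (cy in seq_len(config$max_cycles)) {
    feed_pool <- list(volume = config$load_cv * Vm_iex,
                      mass = feed_conc * config$load_cv * Vm_iex,
                      modifier = config$iex_load_modifier)
    iex_load_mass <- iex_pool$mass + feed_pool$mass
    sched <- iccc_load_schedule(list(recycle = iex_pool), feed_pool,
                                config$load_flow_cv, Vm_iex,
                                config$iex_load_modifier)
    load_sim <- sim_mod(config$iex, feed, sched)
    elu_sim <- sim_mod(config$iex, feed, config$iex_protocol,
                       initial_state = load_sim$final_state)
    fr_iex <- fractionate(elu_sim$chromatogram, config$iex_cuts, Vm_iex)
    ## route IEX fractions
    dest <- config$routing
    pools_next <- list(iex = empty_pool(protein), hic = empty_pool(protein),
                       product = empty_pool(protein),
                       waste = fr_iex[[1L]])
    for (k in 1:3) {
      d <- dest[[paste0("iex_f", k)]]
      pools_next[[d]] <- add_pool(pools_next[[d]], fr_iex[[k + 1L]])
    }
    ## HIC load: its recycle pool + transferred IEX material
    hic_in <- add_pool(hic_pool, pools_next$hic)
    hic_sched <- iccc_load_schedule(list(transfer = hic_in), NULL,
                                    config$load_flow_cv, Vm_hic,
                                    config$hic_load_modifier)
    hic_fracs <- rep(list(empty_pool(protein)), 4L)
    hic_elu <- NULL
    if (!is.null(hic_sched)) {
      hic_load_sim <- sim_mod(config$hic, feed, hic_sched)
      hic_elu <- sim_mod(config$hic, feed, config$hic_protocol,
                         initial_state = hic_load_sim$final_state)
      hic_fracs <- fractionate(hic_elu$chromatogram, config$hic_cuts,
                               Vm_hic)
    }
    pools_hic_next <- list(iex = empty_pool(protein),
                           hic = empty_pool(protein),
                           product = empty_pool(protein),
                           waste = hic_fracs[[1L]])
    for (k in 1:3) {
      d <- dest[[paste0("hic_f", k)]]
      pools_hic_next[[d]] <- add_pool(pools_hic_next[[d]], hic_fracs[[k + 1L]])
    }
    iex_pool <- add_pool(pools_next$iex, pools_hic_next$iex)
    hic_pool <- pools_hic_next$hic
    product_pool <- add_pool(pools_next$product, pools_hic_next$product)
    cycles[[cy]] <- list(
      cycle = cy,
      iex_loaded_mg = iex_load_mass,
      iex_eluted_mg = stats::setNames(
        Reduce(`+`, lapply(fr_iex, `[[`, "mass")), protein),
      iex_fractions = fr_iex, hic_fractions = hic_fracs,
      product_mg = product_pool$mass,
      recycle_iex_mg = iex_pool$mass, recycle_hic_mg = hic_pool$mass,
      waste_mg = pools_next$waste$mass + pools_hic_next$waste$mass,
      iex_overloaded = unname(iex_load_mass[prod]) > iex_capacity_mg,
      iex_chromatogram = elu_sim$chromatogram,
      hic_chromatogram = if (!is.null(hic_elu)) hic_elu$chromatogram)
    ss <- detect_cyclic_steady_state(cycles,
                                     config$steady_state_tolerance)
    if (ss$reached && cy >= 2L) break
  }
  ## accumulation: the IEX recycle pool's product content grows cycle over
  ## cycle, or the column is loaded beyond its static capacity
  rec <- vapply(cycles, function(x) unname(x$recycle_iex_mg[prod]),
                numeric(1))
  growing <- length(rec) >= 3L &&
    all(diff(utils::tail(rec, 3L)) > 0) &&
    utils::tail(rec, 1L) > 1.1 * utils::tail(rec, 3L)[1L]
  overloaded <- any(vapply(cycles, `[[`, logical(1), "iex_overloaded"))
  ss <- detect_cyclic_steady_state(cycles, config$steady_state_tolerance)
  structure(list(cycles = cycles,
                 accumulation_detected = growing || overloaded,
                 steady_state = ss,
                 product_mg = cycles[[length(cycles)]]$product_mg),
            class = "mc_iccc_result")
}

#' @export
print.mc_iccc_result <- function(x, ...) {
  cat(sprintf("iCCC run: %d cycles, steady state %s, accumulation %s\n",
              length(x$cycles),
              if (x$steady_state$reached)
                sprintf("at cycle %d", x$steady_state$cycle_index)
              else "not reached",
              if (x$accumulation_detected) "DETECTED" else "not detected"))
  invisible(x)
}

#' Detect a cyclic steady state from per-cycle results
#'
#' Steady when every monitored per-fraction mass (product, IEX recycle,
#' HIC recycle) changes by no more than `tolerance` (relative) between two
#' consecutive cycles.
#'
#' @param results list of per-cycle results from [run_iccc()].
#' @param tolerance relative change threshold.
#' @return List with `reached` (logical) and `cycle_index` (first steady
#'   cycle, or `NA`).
#' @export
detect_cyclic_steady_state <- function(results, tolerance = 0.03) {
  if (length(results) < 2L)
    return(list(reached = FALSE, cycle_index = NA_integer_))
  key <- function(x) c(sum(x$product_mg), sum(x$recycle_iex_mg),
                       sum(x$recycle_hic_mg))
  for (k in 2:length(results)) {
    a <- key(results[[k - 1L]]); b <- key(results[[k]])
    rel <- abs(b - a) / pmax(abs(a), 1e-9)
    ## fractions that are essentially empty in both cycles are steady
    rel[abs(a) < 1e-6 & abs(b) < 1e-6] <- 0
    if (all(rel <= tolerance))
      return(list(reached = TRUE, cycle_index = k))
  }
  list(reached = FALSE, cycle_index = NA_integer_)
}
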