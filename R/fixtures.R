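#' Laboratory-scale ("Nano"-type) module geometry preset
#'
#' A 3 mL membrane module with 8 mm bed height and total voidage 0.8.  The
#' internal zone dimensions of such devices are not published; the preset
#' distributes 16 percent of the membrane volume over the hold-up zones
#' (2/6/6/2 percent for inlet pipe, annular gap, inner cylinder, outlet
#' pipe), giving a membrane porosity of 0.64.
#'
#' @param Vm membrane volume, mL.
#' @return A [module_geometry()].
#' @export
nano_geometry <- function(Vm = 3) module_geometry(Vm = Vm, bed_height = 8,
                                                  eps = 0.8)

#' SYNTHETIC ion-exchange isotherm preset
#'
#' Plausible salt-dependent competitive Langmuir parameters for a cation
#' exchanger binding an antibody (component 1), a weak binder (2) and a
#' strong binder (3): binding weakens with ammonium sulfate (negative Henry
#' exponents), capacities of a few tens of g/L membrane.  These values are
#' SYNTHETIC: they are invented for testing and demonstration, not fitted
#' to any experimental data.
#'
#' @param kla lumped mass-transfer coefficient, 1/min.
#' @return An [isotherm_params()] with attribute `synthetic = TRUE`.
#' @export
synthetic_iex_isotherm <- function(kla = 6) {
  ## selectivity design: elution order weak binder < product < strong
  ## binder on an ascending salt gradient, with the strong binder only
  ## mildly stronger than the product at load salt (minor congener), so
  ## sequential loading shows capture, not displacement chromatography
  p <- isotherm_params(a1 = c(-30, -20, -25), a2 = c(50, 40, 55),
                       b1 = c(0.2, 0.08, 1.4), b2 = c(-1.4, -1.1, -1.0),
                       L1 = 0, kla = kla, cmod_range = c(0.005, 1.2),
                       component_names = c("product", "weak_binder",
                                           "strong_binder"))
  attr(p, "synthetic") <- TRUE
  p
}

#' SYNTHETIC hydrophobic-interaction isotherm preset
#'
#' Counterpart of [synthetic_iex_isotherm()] for a hydrophobic-interaction
#' membrane: binding strengthens with ammonium sulfate (positive Henry
#' exponents) and the additional linear term `L1` is active.  SYNTHETIC
#' values, not fitted to any experimental data.
#'
#' @param kla lumped mass-transfer coefficient, 1/min.
#' @return An [isotherm_params()] with attribute `synthetic = TRUE`.
#' @export
synthetic_hic_isotherm <- function(kla = 6) {
  ## descending-gradient elution order: weak binder, product, strong binder
  p <- isotherm_params(a1 = c(25, 15, 20), a2 = c(25, 20, 30),
                       b1 = c(40, 25, 30), b2 = c(2, 2.6, 1.2),
                       L1 = 2, kla = kla, cmod_range = c(0, 1.2),
                       component_names = c("product", "weak_binder",
                                           "strong_binder"))
  attr(p, "synthetic") <- TRUE
  p
}

#' Fixture specification for the synthetic-data generators
#'
#' Bundles the deterministic presets that stand in for the measurements a
#' module characterization would normally provide: module geometry,
#' per-zone dispersion, a SYNTHETIC isotherm, the feed composition, the
#' noise level and the seed.
#'
#' @param seed integer seed; fixed seed implies identical outputs.
#' @param geometry a [module_geometry()] (default [nano_geometry()]).
#' @param fluidics a [zone_fluidics()] (default: the fitted laboratory
#'   dispersion set 9e-4 / 9e-4 / 5e-3 / 250 / 250 cm^2/s).
#' @param isotherm an [isotherm_params()] (default
#'   [synthetic_iex_isotherm()]).
#' @param feed_preset `"validation"` (1 g/L product + 0.2 g/L total side
#'   components), `"case_study"` (5 g/L + 1 g/L) or `"zero"`.
#' @param noise_cv multiplicative Gaussian noise level (coefficient of
#'   variation, e.g. 0.05 for 5 percent); 0 disables noise.
#' @param resolution cells per zone for generator simulations.
#' @return An object of class `mc_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, geometry = nano_geometry(),
                         fluidics = zone_fluidics(),
                         isotherm = synthetic_iex_isotherm(),
                         feed_preset = c("validation", "case_study", "zero"),
                         noise_cv = 0,
                         resolution = c(8L, 8L, 12L, 8L, 8L)) {
  feed_preset <- match.arg(feed_preset)
  check_number(noise_cv, "noise_cv", lower = 0)
  structure(list(seed = as.integer(seed), geometry = geometry,
                 fluidics = fluidics, isotherm = isotherm,
                 feed_preset = feed_preset, noise_cv = noise_cv,
                 resolution = resolution),
            class = "mc_fixture_spec")
}

#' Three-component feed preset
#'
#' @param spec a [fixture_spec()]; `spec$feed_preset` selects the
#'   composition: `"validation"` gives 1 g/L product with 0.1 + 0.1 g/L
#'   side components, `"case_study"` gives 5 g/L with 0.5 + 0.5 g/L,
#'   `"zero"` an all-zero feed.
#' @return A [component_system()] with product, weak binder, strong binder
#'   and the modifier.
#' @export
make_feed <- function(spec = fixture_spec()) {
  conc <- switch(spec$feed_preset,
                 validation = c(1, 0.1, 0.1, 0),
                 case_study = c(5, 0.5, 0.5, 0),
                 zero = c(0, 0, 0, 0))
  component_system(
    list(component(1L, "product", "product"),
         component(2L, "weak_binder", "weak_binder"),
         component(3L, "strong_binder", "strong_binder"),
         component(4L, "modifier", "modifier")),
    feed_concentrations = conc)
}

## single non-binding tracer (+ no modifier) system
tracer_system <- function() {
  component_system(list(component(1L, "tracer", "tracer")),
                   feed_concentrations = 5)
}

#' Generate a synthetic tracer outlet curve from the zonal model
#'
#' Injects a short non-binding tracer pulse (5 g/L) into the module and
#' records the outlet curve, optionally with multiplicative detector noise.
#' The attribute `t_instrument` carries the mean time of the inlet pulse
#' (the quantity a blank run measures), and `truth` the generating ground
#' truth, so moment analysis can be validated round-trip.
#'
#' @param spec a [fixture_spec()].
#' @param flow volumetric flow, mL/min.
#' @param pulse_cv injection duration, CV.
#' @param delay_cv tracer-free acquisition window before the injection, CV
#'   (provides the leading baseline a real detector trace has).
#' @param total_cv total recorded volume, CV (must cover the tail).
#' @param dt_report reporting interval, min.
#' @return A [tracer_curve()] with attributes `t_instrument` and `truth`.
#' @export
make_tracer_curve <- function(spec = fixture_spec(), flow = 1,
                              pulse_cv = 0.05, delay_cv = 1,
                              total_cv = 10, dt_report = NULL) {
  geo <- spec$geometry
  flow_cv <- flow / geo$Vm
  dt_report <- dt_report %||% max(total_cv / flow_cv / 900, 5e-4)
  sched <- process_schedule(
    operating_step("baseline", delay_cv, flow_cv),
    operating_step("inject", pulse_cv, flow_cv,
                   inlet = c(tracer = 5)),
    operating_step("wash", total_cv - pulse_cv - delay_cv, flow_cv))
  sim <- simulate_module(geo, spec$fluidics, tracer_system(), sched,
                         resolution = spec$resolution,
                         dt_report = dt_report)
  sig <- sim$chromatogram$conc[, "tracer"]
  if (spec$noise_cv > 0) {
    set.seed(spec$seed)
    sig <- pmax(sig * (1 + spec$noise_cv * stats::rnorm(length(sig))), 0)
  }
  cv <- tracer_curve(sim$chromatogram$time, sig, flow = flow)
  ## everything upstream of the module: delay plus pulse first moment
  t_pulse <- (delay_cv + pulse_cv / 2) / flow_cv
  attr(cv, "t_instrument") <- t_pulse
  attr(cv, "truth") <- list(eps = geo$eps, Vm = geo$Vm,
                            accessible_volume = geo$eps * geo$Vm,
                            simulation = sim)
  cv
}

## finite-bath equilibrium: solve c + (V_ads / V_liq) * q(c, cmod) = c0
## (damped Newton with a numerical Jacobian, nb unknowns)
bath_equilibrium <- function(c0, cmod, params, V_liq, V_ads) {
  phi <- V_ads / V_liq
  f <- function(c) c + phi * as.numeric(qstar_matrix(matrix(c, 1), cmod,
                                                     params)) - c0
  c <- pmin(c0, c0 / (1 + phi * 10))       # start below the feed
  c[c0 == 0] <- 0
  for (it in 1:200) {
    r <- f(c)
    if (max(abs(r)) < 1e-12 * max(1, max(c0))) return(pmax(c, 0))
    n <- length(c)
    J <- matrix(0, n, n)
    h <- pmax(abs(c), 1e-6) * 1e-7
    for (j in seq_len(n)) {
      cj <- c; cj[j] <- cj[j] + h[j]
      J[, j] <- (f(cj) - r) / h[j]
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step))
      stopf("no finite-bath equilibrium found (singular Jacobian): unphysical preset?")
    lambda <- 1
    repeat {
      cn <- c - lambda * step
      cn <- pmax(cn, 0)
      if (max(abs(f(cn))) < max(abs(r)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    c <- cn
  }
  if (max(abs(f(c))) > 1e-6 * max(1, max(c0)))
    stopf("finite-bath equilibrium iteration did not converge: unphysical preset?")
  pmax(c, 0)
}

#' Generate a synthetic batch-adsorption dataset
#'
#' For every modifier level and feed dilution, the supernatant and loading
#' are solved self-consistently from the competitive Langmuir equilibrium
#' and the finite-bath mass balance; elution concentrations are generated
#' loss-free, so binding and elution mass balances agree by construction.
#' Multiplicative noise (from `spec$noise_cv`, seeded) is applied to the
#' measured supernatant concentrations only.
#'
#' @param spec a [fixture_spec()] (its isotherm is the generating truth).
#' @param modifier_levels modifier concentrations, mol/L.
#' @param feed_fractions feed volume fractions of the bath (e.g.
#'   `c(1, 2, 3, 5, 6) / 6`).
#' @param feed_conc per-component feed concentrations at full strength,
#'   g/L (default: case-study feed, binding components only).  A matrix
#'   (one row per feed mixture) generates a concentration-ratio-varied
#'   design: a single culture-derived feed leaves the side components'
#'   capacity parameters weakly identified, so accurate competitive
#'   parameter determination needs ratio variation.
#' @param V_total bath liquid volume, mL.
#' @param V_ads adsorptive membrane volume, mL (a 13 mm single-layer
#'   membrane disc is about 0.037 mL).
#' @param resin_label label carried on the dataset.
#' @return An [isotherm_dataset()].
#' @export
make_isotherm_dataset <- function(spec = fixture_spec(),
                                  modifier_levels = c(0.02, 0.05, 0.1,
                                                      0.15, 0.2, 0.3),
                                  feed_fractions = c(1, 2, 3, 5, 6) / 6,
                                  feed_conc = c(5, 0.5, 0.5),
                                  V_total = 5, V_ads = 0.037,
                                  resin_label = "IEX") {
  if (!length(modifier_levels) || !length(feed_fractions))
    stopf("modifier levels and feed fractions must be non-empty")
  params <- spec$isotherm
  feed_conc <- if (is.matrix(feed_conc)) feed_conc else
    matrix(feed_conc, nrow = 1L)
  set.seed(spec$seed)
  pts <- list()
  for (cm in modifier_levels) for (fr in feed_fractions)
    for (row in seq_len(nrow(feed_conc))) {
    c0 <- feed_conc[row, ] * fr
    ceq <- bath_equilibrium(c0, cm, params, V_total, V_ads)
    q <- (c0 - ceq) * V_total / V_ads
    cel <- q * V_ads / V_total            # loss-free elution into V_total
    noisy <- function(x) if (spec$noise_cv > 0)
      pmax(x * (1 + spec$noise_cv * stats::rnorm(length(x))), 0) else x
    pts[[length(pts) + 1L]] <-
      batch_point(c_feed = c0, c_star_binding = noisy(ceq),
                  c_star_elution = noisy(cel), V_total = V_total,
                  V_ads = V_ads, c_mod = cm,
                  tolerance = max(0.05, 6 * spec$noise_cv))
  }
  ds <- isotherm_dataset(pts, resin_label = resin_label)
  attr(ds, "synthetic") <- TRUE
  attr(ds, "truth") <- params
  ds
}

#' iCCC fixture: coupled IEX + HIC modules with hand-picked cut points
#'
#' Builds a complete [iccc_config()] around the synthetic isotherm presets
#' in two variants.  `"tailing"` uses the laboratory module's zonal fluid
#' dynamics (stirred-tank outlet zones, sharp front / long tail); its cut
#' points follow the only workable choice for such peaks, a front fraction
#' that contains the product bulk and is recycled onto the ion exchanger.
#' `"symmetric"` emulates a membrane stack in a plain column (negligible
#' hold-up zones, uniform low dispersion, near-symmetric peaks); its cut
#' points place the product bulk in the transfer fraction.  Elution runs at
#' 1 CV/min with an 8 CV gradient; fresh feed is 2 CV per cycle.
#'
#' @param variant `"tailing"` or `"symmetric"`.
#' @param max_cycles cycles to run.
#' @return List with `config` (an [iccc_config()]) and `feed`.
#' @export
iccc_fixture <- function(variant = c("tailing", "symmetric"),
                         max_cycles = 5) {
  variant <- match.arg(variant)
  iex_iso <- synthetic_iex_isotherm()
  hic_iso <- synthetic_hic_isotherm()
  if (variant == "tailing") {
    geo <- nano_geometry()
    flu <- zone_fluidics()
    res <- c(6L, 6L, 10L, 6L, 6L)
    iex_cuts <- c(1, 6, 9)        # front fraction holds the product bulk
    hic_cuts <- c(2, 8, 11)
  } else {
    geo <- module_geometry(3, 8, eps = (0.004 + 0.64 * 3) / 3,
                           zone_volumes = rep(0.001, 4),
                           zone_lengths = c(0.1, 0.1, 0.8, 0.1, 0.1))
    flu <- zone_fluidics(rep(9e-4, 5))
    res <- c(1L, 2L, 16L, 2L, 1L)
    iex_cuts <- c(1, 4.3, 8)      # product bulk goes to the transfer cut
    hic_cuts <- c(2, 8, 11)
  }
  iex <- module_config(geo, flu, iex_iso, resolution = res)
  hic <- module_config(geo, flu, hic_iso, resolution = res)
  iex_protocol <- process_schedule(
    operating_step("wash", 2, 1, modifier_start = 0.02),
    operating_step("gradient", 8, 1, modifier_start = 0.02,
                   modifier_end = 0.7),
    operating_step("regenerate", 2, 1, modifier_start = 1),
    operating_step("equilibrate", 2, 1, modifier_start = 0.02))
  hic_protocol <- process_schedule(
    operating_step("wash", 2, 1, modifier_start = 1),
    operating_step("gradient", 8, 1, modifier_start = 1,
                   modifier_end = 0.05),
    operating_step("regenerate", 2, 1, modifier_start = 0),
    operating_step("equilibrate", 2, 1, modifier_start = 1))
  config <- iccc_config(iex, hic, iex_protocol, hic_protocol,
                        load_cv = 2, load_flow_cv = 1,
                        iex_cuts = iex_cuts, hic_cuts = hic_cuts,
                        iex_load_modifier = 0.02, hic_load_modifier = 1,
                        max_cycles = max_cycles)
  list(config = config, feed = make_feed(fixture_spec()))
}
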