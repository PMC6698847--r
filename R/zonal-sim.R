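## ---- state layout -------------------------------------------------------
## y = [ c : NL * nc liquid concentrations, column-major by component
##     | q : Nm * nb membrane loadings, column-major by binding component ]

state_layout <- function(grid, system, has_isotherm = TRUE) {
  roles <- cs_roles(system)
  nc <- length(roles)
  bind <- if (has_isotherm) cs_binding_indices(system) else integer(0)
  list(NL = grid$NL, Nm = grid$Nm, nc = nc,
       bind = bind, nb = length(bind),
       mod = cs_modifier_index(system),
       names = cs_names(system),
       n_state = grid$NL * nc + grid$Nm * length(bind))
}

## equilibrium loading used inside the solver: clamps the modifier into the
## declared validity range and floors qmax, so transient solver excursions
## cannot produce NaNs
qstar_sim <- function(cmat, cmod, params) {
  cmod <- pmin(pmax(cmod, params$cmod_range[1]), params$cmod_range[2])
  cmat <- pmax(cmat, 0)
  n <- length(params$a2)
  qmax <- pmax(outer(cmod, params$a1) + rep(params$a2, each = length(cmod)),
               1e-6)
  H <- outer(cmod, seq_len(n),
             function(cm, j) params$b1[j] * cm^params$b2[j])
  denom <- 1 + rowSums(H / qmax * cmat)
  H * cmat / denom + params$L1 * cmod * cmat
}

#' Assemble the zonal model right-hand side for a fixed flow
#'
#' Builds the semi-discretized model (transport operator plus adsorption
#' coupling) for one operating condition.  Mostly used internally by
#' [simulate_module()]; exposed for inspection and testing.
#'
#' @param geometry a [module_geometry()].
#' @param fluidics a [zone_fluidics()].
#' @param system a [component_system()].
#' @param flow volumetric flow, mL/min (>= 0).
#' @param isotherm optional [isotherm_params()] for the binding components.
#' @param resolution cells per zone, see [build_grid()].
#' @param kinetics `"ldf"` (default): linear-driving-force solid balance
#'   `dq/dt = kla (q*(c, cmod) - q)` with the matching liquid sink
#'   `-(1/eps_mem) dq/dt`, which conserves mass and reproduces the Langmuir
#'   equilibrium at steady state.  `"literal"`: the liquid sink is written
#'   directly as `kla (c - q*)` for sensitivity checks.
#' @return An object of class `mc_zonal_model`.
#' @export
build_zonal_model <- function(geometry, fluidics, system, flow,
                              isotherm = NULL,
                              resolution = c(20L, 20L, 30L, 20L, 20L),
                              kinetics = c("ldf", "literal")) {
  kinetics <- match.arg(kinetics)
  grid <- build_grid(geometry, resolution)
  layout <- state_layout(grid, system, has_isotherm = !is.null(isotherm))
  if (layout$nb > 0L && !is.null(isotherm) &&
      length(isotherm$a2) != layout$nb)
    stopf("isotherm has %d components but the system has %d binding components",
          length(isotherm$a2), layout$nb)
  tr <- build_transport(grid, fluidics, flow)
  structure(list(grid = grid, layout = layout, transport = tr,
                 isotherm = isotherm, kinetics = kinetics,
                 geometry = geometry, fluidics = fluidics, system = system),
            class = "mc_zonal_model")
}

#' Zonal model right-hand side
#'
#' Time derivative of the full state (liquid concentrations in every cell of
#' every zone, membrane loadings in every membrane cell) under the model's
#' transport operator, inlet boundary condition and adsorption kinetics.
#'
#' @param t time, min.
#' @param state numeric state vector (see [build_zonal_model()]).
#' @param model an `mc_zonal_model`.
#' @param cin inlet concentration vector (one per component), or a function
#'   of time returning one.
#' @return Numeric vector `d(state)/dt`.
#' @export
zonal_rhs <- function(t, state, model, cin = NULL) {
  lay <- model$layout
  if (length(state) != lay$n_state)
    stopf("state has length %d, expected %d", length(state), lay$n_state)
  if (any(!is.finite(state))) {
    bad <- which(!is.finite(state))[1L]
    if (bad <= lay$NL * lay$nc) {
      cell <- (bad - 1L) %% lay$NL + 1L
      stopf("non-finite state in zone %d, cell %d",
            model$grid$zone_of_cell[cell], cell)
    }
    stopf("non-finite membrane loading state (index %d)", bad)
  }
  cin_t <- if (is.function(cin)) cin(t) else cin %||% numeric(lay$nc)
  C <- matrix(state[seq_len(lay$NL * lay$nc)], lay$NL, lay$nc)
  dC <- as.matrix(model$transport$M %*% C)
  b <- model$transport$b
  nz <- which(b != 0)
  if (length(nz))
    dC[nz, ] <- dC[nz, ] + outer(b[nz], cin_t)
  dQ <- numeric(0)
  if (lay$nb > 0L && !is.null(model$isotherm)) {
    iso <- model$isotherm
    i3 <- model$grid$idx$z3
    cmem <- C[i3, lay$bind, drop = FALSE]
    cmod <- if (is.na(lay$mod)) rep(0, lay$Nm) else C[i3, lay$mod]
    qs <- qstar_sim(cmem, cmod, iso)
    Qm <- matrix(state[lay$NL * lay$nc + seq_len(lay$Nm * lay$nb)],
                 lay$Nm, lay$nb)
    eps_mem <- model$geometry$eps_mem
    if (model$kinetics == "ldf") {
      dQ <- iso$kla * (qs - Qm)
      dC[i3, lay$bind] <- dC[i3, lay$bind] - dQ / eps_mem
    } else {
      ## literal form: liquid sink kla * (c - q*); the removed mass is
      ## booked into q so the overall balance can still be audited
      sink <- iso$kla * (pmax(cmem, 0) - qs)
      dC[i3, lay$bind] <- dC[i3, lay$bind] - sink
      dQ <- sink * eps_mem
    }
  }
  c(as.numeric(dC), as.numeric(dQ))
}

## ---- schedule integration ----------------------------------------------

## expand an operating step into (flow mL/min, duration min, cin function)
step_plan <- function(step, geometry, layout) {
  Q <- step$flow_cv * geometry$Vm
  dur <- step$duration_cv / step$flow_cv
  cin0 <- numeric(layout$nc)
  if (length(step$inlet)) {
    pos <- match(names(step$inlet), layout$names)
    if (anyNA(pos))
      stopf("step '%s' feeds unknown component(s): %s", step$name,
            paste(names(step$inlet)[is.na(pos)], collapse = ", "))
    cin0[pos] <- step$inlet
  }
  ms <- step$modifier_start; me <- step$modifier_end
  has_mod <- !is.na(layout$mod)
  cin <- function(t) {
    v <- cin0
    if (has_mod) v[layout$mod] <- ms + (me - ms) * min(max(t / dur, 0), 1)
    v
  }
  list(Q = Q, dur = dur, cin = cin, name = step$name)
}

#' Simulate a membrane module over an operating schedule
#'
#' Integrates the five-zone model over the steps of a schedule with
#' step-wise inlet boundary conditions (and linear modifier gradients within
#' steps), using a stiff sparse ODE solver.  Concentrations are clipped at
#' zero only in the reported chromatogram, never in the solver state.
#'
#' @inheritParams build_zonal_model
#' @param schedule a [process_schedule()].
#' @param initial_state optional state vector from a previous simulation
#'   (partially loaded module); defaults to a clean module equilibrated at
#'   the first step's starting modifier concentration.
#' @param inlet_fun optional function `f(t_global) -> conc vector` that
#'   overrides the schedule's inlet composition (used to chain modules).
#' @param dt_report reporting interval, min (default 1 s).
#' @param rtol,atol solver tolerances (relative, absolute in g/L).
#' @return An object of class `mc_simulation` with elements `chromatogram`
#'   (class `mc_chromatogram`), `mass_balance` (data frame: injected,
#'   eluted, retained change and closure per component), `final_state`,
#'   `bound_mass` (membrane-bound mass per binding component at the end, g),
#'   `steps` (step boundary times) and solver `diagnostics`.
#' @export
simulate_module <- function(geometry, fluidics, system, schedule,
                            isotherm = NULL,
                            resolution = c(20L, 20L, 30L, 20L, 20L),
                            kinetics = c("ldf", "literal"),
                            initial_state = NULL, inlet_fun = NULL,
                            dt_report = 1 / 60, rtol = 1e-6, atol = 1e-9) {
  kinetics <- match.arg(kinetics)
  if (!inherits(schedule, "mc_schedule"))
    stopf("'schedule' must be a process_schedule")
  grid <- build_grid(geometry, resolution)
  layout <- state_layout(grid, system, has_isotherm = !is.null(isotherm))
  y <- initial_state %||% {
    y0 <- numeric(layout$n_state)
    if (!is.na(layout$mod)) {
      m0 <- schedule$steps[[1L]]$modifier_start
      y0[(layout$mod - 1L) * layout$NL + seq_len(layout$NL)] <- m0
    }
    y0
  }
  if (length(y) != layout$n_state)
    stopf("initial_state has length %d, expected %d", length(y),
          layout$n_state)
  retained0 <- state_inventory(y, grid, layout)
  t_global <- 0
  times_all <- conc_all <- flow_all <- NULL
  bound_tr <- NULL
  injected <- numeric(layout$nc)
  steps_info <- data.frame(name = character(0), t_start = numeric(0),
                           t_end = numeric(0), flow = numeric(0))
  n_accept <- 0L
  for (step in schedule$steps) {
    plan <- step_plan(step, geometry, layout)
    model <- build_zonal_model(geometry, fluidics, system, plan$Q,
                               isotherm = isotherm, resolution = resolution,
                               kinetics = kinetics)
    times <- seq(0, plan$dur, by = dt_report)
    if (plan$dur - times[length(times)] > 1e-9 * plan$dur)
      times <- c(times, plan$dur)
    else times[length(times)] <- plan$dur
    cin <- if (is.null(inlet_fun)) plan$cin else {
      t0 <- t_global
      function(t) inlet_fun(t0 + t)
    }
    sol <- deSolve::ode(y = y, times = times,
                        func = function(t, y, p) list(zonal_rhs(t, y, model,
                                                                cin)),
                        parms = NULL, method = "lsodes",
                        rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1L] < 0)
      stopf("solver failed in step '%s' at t = %.4g min (global %.4g min)",
            step$name, sol[nrow(sol), 1L], t_global + sol[nrow(sol), 1L])
    n_accept <- n_accept + attr(sol, "istate")[3L]
    y <- as.numeric(sol[nrow(sol), -1L])
    ## inlet mass this step: integrate Q * cin(t) on the reporting grid
    cin_mat <- do.call(rbind, lapply(times, cin))
    for (k in seq_len(layout$nc))
      injected[k] <- injected[k] + plan$Q * trapz(times, cin_mat[, k])
    out_idx <- 1L + (seq_len(layout$nc) - 1L) * layout$NL +
      model$transport$outlet
    ## drop the first row of continuation steps (shared boundary point)
    keep <- if (is.null(times_all)) seq_len(nrow(sol))
            else seq.int(2L, nrow(sol))
    times_all <- c(times_all, t_global + sol[keep, 1L])
    conc_all <- rbind(conc_all, sol[keep, out_idx, drop = FALSE])
    flow_all <- c(flow_all, rep(plan$Q, length(keep)))
    if (layout$nb > 0L) {
      bm <- vapply(seq_len(layout$nb), function(bk) {
        cols <- 1L + layout$NL * layout$nc + (bk - 1L) * grid$Nm +
          seq_len(grid$Nm)
        rowSums(sol[keep, cols, drop = FALSE]) * grid$vcell_mem_total
      }, numeric(length(keep)))
      bound_tr <- rbind(bound_tr, matrix(bm, nrow = length(keep)))
    }
    steps_info <- rbind(steps_info,
                        data.frame(name = step$name, t_start = t_global,
                                   t_end = t_global + plan$dur,
                                   flow = plan$Q))
    t_global <- t_global + plan$dur
  }
  ## keep time strictly increasing (step boundaries are shared points)
  ord <- order(times_all)
  times_all <- times_all[ord]; conc_all <- conc_all[ord, , drop = FALSE]
  flow_all <- flow_all[ord]
  dup <- c(FALSE, diff(times_all) <= 0)
  times_all <- times_all[!dup]; conc_all <- conc_all[!dup, , drop = FALSE]
  flow_all <- flow_all[!dup]
  colnames(conc_all) <- layout$names
  mod_trace <- if (!is.na(layout$mod)) pmax(conc_all[, layout$mod], 0)
               else rep(0, length(times_all))
  chrom <- chromatogram(time = times_all,
                        conc = pmax(conc_all[, setdiff(seq_len(layout$nc),
                                                       layout$mod),
                                             drop = FALSE], 0),
                        modifier = mod_trace, flow = flow_all)
  eluted <- vapply(seq_len(layout$nc), function(k)
    trapz(times_all, flow_all * pmax(conc_all[, k], 0)), numeric(1))
  retained1 <- state_inventory(y, grid, layout)
  d_ret <- retained1 - retained0
  closure <- ifelse(injected > 0,
                    abs(injected - eluted - d_ret) / injected, NA_real_)
  mb <- data.frame(component = layout$names,
                   injected_mg = injected, eluted_mg = eluted,
                   retained_change_mg = d_ret, closure = closure)
  bound <- bound_mass_from_state(y, grid, layout)
  bound_trace <- if (layout$nb > 0L) {
    bt <- bound_tr[ord, , drop = FALSE][!dup, , drop = FALSE]
    df <- data.frame(time = times_all)
    df[layout$names[layout$bind]] <- as.data.frame(bt)
    df
  } else NULL
  structure(list(chromatogram = chrom, mass_balance = mb,
                 final_state = y, bound_mass = bound, bound_trace = bound_trace,
                 steps = steps_info, grid = grid, layout = layout,
                 diagnostics = list(solver_steps = n_accept,
                                    rtol = rtol, atol = atol)),
            class = "mc_simulation")
}

## total mass (mg) per component currently in the module (liquid + bound)
state_inventory <- function(y, grid, layout) {
  C <- matrix(y[seq_len(layout$NL * layout$nc)], layout$NL, layout$nc)
  inv <- as.numeric(crossprod(C, grid$V_liq))
  if (layout$nb > 0L) {
    Qm <- matrix(y[layout$NL * layout$nc + seq_len(grid$Nm * layout$nb)],
                 grid$Nm, layout$nb)
    inv[layout$bind] <- inv[layout$bind] +
      colSums(Qm) * grid$vcell_mem_total
  }
  stats::setNames(inv, layout$names)
}

## membrane-bound mass (mg) per binding component
bound_mass_from_state <- function(y, grid, layout) {
  if (layout$nb == 0L) return(numeric(0))
  Qm <- matrix(y[layout$NL * layout$nc + seq_len(grid$Nm * layout$nb)],
               grid$Nm, layout$nb)
  stats::setNames(colSums(Qm) * grid$vcell_mem_total,
                  layout$names[layout$bind])
}

#' @export
print.mc_simulation <- function(x, ...) {
  cat(sprintf("Zonal model simulation: %d steps, %.3g min, %d report points\n",
              nrow(x$steps), max(x$chromatogram$time),
              length(x$chromatogram$time)))
  cat("Mass balance (mg):\n")
  print(x$mass_balance, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.mc_simulation <- function(x, ...) plot(x$chromatogram, ...)
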