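## Independent 1-D general-rate column reference implementation.
## Deliberately coded separately from the package internals (loop-based
## finite volumes, dense lsoda): a single membrane column of volume Vm,
## length L, porosity eps, fed at flow Q with upwind advection, central
## dispersion (closed-vessel ends) and optional linear-driving-force
## Langmuir binding.  Used as the oracle for the degenerate-geometry
## equivalence of the zonal model.
reference_column_sim <- function(Vm, L, eps, Dax_cm2s, Q, n_cells,
                                 times, cin_fun, isotherm = NULL,
                                 cmod = 0, rtol = 1e-8, atol = 1e-11) {
  A <- Vm / L
  dx <- L / n_cells
  Vliq <- eps * Vm / n_cells
  Vtot <- Vm / n_cells
  D <- Dax_cm2s * 60
  Econd <- D * A * eps / dx
  nb <- if (is.null(isotherm)) 0L else length(isotherm$a2)
  rhs <- function(t, y, p) {
    nc <- max(1L, nb)
    C <- matrix(y[seq_len(n_cells * nc)], n_cells, nc)
    dC <- matrix(0, n_cells, nc)
    cin <- cin_fun(t)
    for (k in seq_len(nc)) {
      c <- C[, k]
      adv <- Q * (c(cin[k], c[-n_cells]) - c)
      dsp <- numeric(n_cells)
      for (i in seq_len(n_cells)) {
        if (i > 1) dsp[i] <- dsp[i] + Econd * (c[i - 1] - c[i])
        if (i < n_cells) dsp[i] <- dsp[i] + Econd * (c[i + 1] - c[i])
      }
      dC[, k] <- (adv + dsp) / Vliq
    }
    if (nb > 0L) {
      Qm <- matrix(y[n_cells * nc + seq_len(n_cells * nb)], n_cells, nb)
      qmax <- isotherm$a1 * cmod + isotherm$a2
      H <- isotherm$b1 * cmod^isotherm$b2
      Cpos <- pmax(C, 0)
      denom <- 1 + as.numeric(Cpos %*% (H / qmax))
      qs <- sweep(Cpos, 2, H, "*") / denom +
        isotherm$L1 * cmod * Cpos
      dQ <- isotherm$kla * (qs - Qm)
      dC <- dC - dQ * (Vtot / Vliq)
      return(list(c(as.numeric(dC), as.numeric(dQ))))
    }
    list(as.numeric(dC))
  }
  nc <- max(1L, nb)
  y0 <- numeric(n_cells * nc + n_cells * nb)
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  outlet <- sol[, 1 + n_cells * seq_len(nc)]
  list(times = sol[, 1], outlet = as.matrix(outlet))
}
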