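#' Discretize a membrane module into the five-zone finite-volume grid
#'
#' Zones 1 (inlet pipe), 2 (annular gap), 4 (inner cylinder) and 5 (outlet
#' pipe) are 1-D chains of well-mixed cells.  The membrane (zone 3) is
#' discretized as independent radial columns, one per zone-2 cell: the flow
#' split in the annular gap sends an equal share of the feed through each
#' column, and each column discharges into the matching zone-4 cell, so the
#' zone-2 to zone-4 mapping is bijective by construction.
#'
#' @param geometry a [module_geometry()].
#' @param resolution integer length 5: cells per zone `(n1, n2, n3, n4,
#'   n5)`; `n4` must equal `n2` (one merge cell per split cell), `n3` is the
#'   number of radial cells per membrane column.
#' @return An object of class `mc_grid` with cell volumes, indices and the
#'   split/merge mapping.
#' @export
build_grid <- function(geometry, resolution = c(20L, 20L, 30L, 20L, 20L)) {
  if (!inherits(geometry, "mc_geometry"))
    stopf("'geometry' must be a module_geometry")
  n <- as.integer(resolution)
  if (length(n) != 5L || any(n < 1L))
    stopf("'resolution' must be 5 integers >= 1")
  if (n[4] != n[2])
    stopf(paste("zone 4 needs one merge cell per zone-2 split cell",
                "(n4 = %d, n2 = %d): the split/merge mapping must be",
                "bijective"), n[4], n[2])
  n1 <- n[1]; n2 <- n[2]; n3 <- n[3]; n5 <- n[5]
  Nm <- n2 * n3                          # membrane cells
  NL <- n1 + n2 + Nm + n2 + n5           # liquid cells
  V <- geometry$zone_volumes
  ## liquid volume per cell; membrane cells hold eps_mem of their volume
  vcell_mem_total <- V[3] / Nm
  V_liq <- c(rep(V[1] / n1, n1), rep(V[2] / n2, n2),
             rep(geometry$eps_mem * vcell_mem_total, Nm),
             rep(V[4] / n2, n2), rep(V[5] / n5, n5))
  idx <- list(z1 = seq_len(n1),
              z2 = n1 + seq_len(n2),
              z3 = n1 + n2 + seq_len(Nm),
              z4 = n1 + n2 + Nm + seq_len(n2),
              z5 = n1 + n2 + Nm + n2 + seq_len(n5))
  ## membrane column j occupies rows (j-1)*n3 + 1 .. j*n3 of zone 3
  col_of_cell <- rep(seq_len(n2), each = n3)
  zone_of_cell <- rep.int(1:5, c(n1, n2, Nm, n2, n5))
  dx <- geometry$zone_lengths / n
  structure(list(n = n, NL = NL, Nm = Nm, V_liq = V_liq,
                 vcell_mem_total = vcell_mem_total, idx = idx,
                 col_of_cell = col_of_cell, zone_of_cell = zone_of_cell,
                 dx = dx, geometry = geometry,
                 split_to_column = seq_len(n2),   # zone-2 cell j -> column j
                 column_to_merge = seq_len(n2)),  # column j -> zone-4 cell j
            class = "mc_grid")
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("Zonal grid: %d | %d | %dx%d | %d | %d cells (%d liquid cells)\n",
              x$n[1], x$n[2], x$n[2], x$n[3], x$n[4], x$n[5], x$NL))
  invisible(x)
}

#' Split the axial flow at an annular-gap cell
#'
#' Under the constant-resistance assumption every zone-2 cell diverts the
#' same radial flow into the membrane, so the axial flow decreases linearly
#' along the gap and reaches exactly zero after the last cell.
#'
#' @param V_axial_in axial flow entering the cell, mL/min (>= 0).
#' @param grid an [build_grid()] object.
#' @param cell_index position of the cell along zone 2 (1-based).
#' @return List with `V_axial_out` and `V_radial` (mL/min).
#' @export
split_flow <- function(V_axial_in, grid, cell_index) {
  check_number(V_axial_in, "V_axial_in", lower = 0)
  n2 <- grid$n[2]
  if (cell_index < 1L || cell_index > n2)
    stopf("cell_index %d outside 1..%d", cell_index, n2)
  remaining <- n2 - cell_index + 1L
  V_radial <- V_axial_in / remaining
  list(V_axial_out = V_axial_in - V_radial, V_radial = V_radial)
}

#' Merge an axial and a radial stream
#'
#' Flow-weighted mixing at an inner-cylinder cell: the combined flow is the
#' sum of the two flows and the outlet concentration of each component is
#' the flow-weighted average (the two streams need not share a
#' composition).
#'
#' @param axial,radial lists with elements `flow` (mL/min, >= 0) and `conc`
#'   (numeric vector, same length in both streams).
#' @return List with `flow` and `conc` of the merged stream.
#' @export
merge_streams <- function(axial, radial) {
  qa <- axial$flow; qr <- radial$flow
  check_number(qa, "axial$flow", lower = 0)
  check_number(qr, "radial$flow", lower = 0)
  if (qa + qr <= 0)
    stopf("cannot merge two zero-flow streams")
  if (length(axial$conc) != length(radial$conc))
    stopf("the two streams must carry the same components")
  list(flow = qa + qr,
       conc = (qa * axial$conc + qr * radial$conc) / (qa + qr))
}

## Sparse linear transport operator at volumetric flow Q (mL/min):
## d(c)/dt = M c + b * c_in(t).  First-order upwind advection, central
## dispersion within each zone, closed-vessel (advective-only) coupling at
## zone interfaces.
build_transport <- function(grid, fluidics, Q) {
  geo <- grid$geometry
  n1 <- grid$n[1]; n2 <- grid$n[2]; n3 <- grid$n[3]; n5 <- grid$n[5]
  V <- grid$V_liq
  Dm <- fluidics$Dax * 60                 # cm^2/s -> cm^2/min
  A <- geo$zone_areas
  ## dispersive conductances (mL/min) between adjacent cells, per zone
  E <- Dm * A / grid$dx
  E[3] <- Dm[3] * (A[3] / n2) * geo$eps_mem / grid$dx[3]  # per column
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  adv <- function(from, to, q) {          # advective link from -> to
    if (q <= 0) return(invisible())
    add(to, from, q / V[to])
    add(from, from, -q / V[from])
  }
  disp <- function(cells, Ez) {           # chain dispersion within a zone
    if (length(cells) < 2L || Ez <= 0) return(invisible())
    a <- cells[-length(cells)]; b <- cells[-1L]
    add(a, a, -Ez / V[a]); add(a, b, Ez / V[a])
    add(b, b, -Ez / V[b]); add(b, a, Ez / V[b])
  }
  z1 <- grid$idx$z1; z2 <- grid$idx$z2; z3 <- grid$idx$z3
  z4 <- grid$idx$z4; z5 <- grid$idx$z5
  ## zone 1 chain
  if (n1 > 1L) for (k in seq_len(n1 - 1L)) adv(z1[k], z1[k + 1L], Q)
  disp(z1, E[1])
  adv(z1[n1], z2[1L], Q)
  ## zone 2: axial decay + radial offtake into membrane columns
  Qr <- Q / n2
  for (j in seq_len(n2)) {
    qax <- Q * (n2 - j) / n2
    if (j < n2) adv(z2[j], z2[j + 1L], qax)
    col_first <- z3[(j - 1L) * n3 + 1L]
    adv(z2[j], col_first, Qr)
  }
  disp(z2, E[2])
  ## zone 3: independent radial columns
  for (j in seq_len(n2)) {
    cells <- z3[(j - 1L) * n3 + seq_len(n3)]
    if (n3 > 1L) for (k in seq_len(n3 - 1L)) adv(cells[k], cells[k + 1L], Qr)
    disp(cells, E[3])
    adv(cells[n3], z4[j], Qr)             # column discharges into merge cell
  }
  ## zone 4: accumulating axial flow toward the outlet
  for (j in seq_len(n2)) {
    qax <- Q * j / n2
    if (j < n2) adv(z4[j], z4[j + 1L], qax) else adv(z4[n2], z5[1L], qax)
  }
  disp(z4, E[4])
  ## zone 5 chain + module outlet
  if (n5 > 1L) for (k in seq_len(n5 - 1L)) adv(z5[k], z5[k + 1L], Q)
  disp(z5, E[5])
  if (Q > 0) add(z5[n5], z5[n5], -Q / V[z5[n5]])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(grid$NL, grid$NL))
  b <- numeric(grid$NL)
  b[z1[1L]] <- Q / V[z1[1L]]
  list(M = M, b = b, Q = Q, outlet = z5[n5])
}
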