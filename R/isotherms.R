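#' Salt-dependent competitive Langmuir isotherm parameters
#'
#' Parameterizes the adsorption equilibrium used throughout the simulator:
#' \deqn{q_i = \frac{H_i c_i}{1 + \sum_j (H_j / q_{max,j}) c_j} + L_1 c_{mod} c_i}
#' with the maximum capacity and the Henry coefficient depending on the
#' modifier (salt) concentration,
#' \deqn{q_{max,i} = a_{1,i} c_{mod} + a_{2,i}, \qquad
#'       H_i = b_{1,i} c_{mod}^{b_{2,i}}.}
#' On ion exchangers binding weakens with salt (`b2 < 0`, `L1 = 0`); on
#' hydrophobic-interaction media it strengthens (`b2 > 0`) and the extra
#' linear term `L1 * cmod * c` is needed.  The modifier itself never enters
#' the competitive denominator.
#'
#' @param a1,a2 numeric vectors (one entry per binding component):
#'   slope (g/L-membrane per mol/L) and intercept (g/L-membrane) of the
#'   capacity-vs-salt line.
#' @param b1,b2 numeric vectors: coefficient (> 0) and exponent of the Henry
#'   power law in the modifier concentration.
#' @param L1 linear coefficient, 1/(mol/L); 0 for ion exchange.
#' @param kla lumped mass-transfer coefficient, 1/min (> 0).  Combines the
#'   film/pore resistance and the effective interfacial area.
#' @param cmod_range modifier range (mol/L) over which the parameters are
#'   declared valid; `qmax` must stay positive on it.
#' @param component_names optional character vector of component names.
#' @return An object of class `mc_isotherm`.
#' @export
isotherm_params <- function(a1, a2, b1, b2, L1 = 0, kla = 6,
                            cmod_range = c(0, 1), component_names = NULL) {
  n <- length(a2)
  if (length(a1) != n || length(b1) != n || length(b2) != n)
    stopf("a1, a2, b1, b2 must have equal length (one entry per component)")
  if (any(!is.finite(c(a1, a2, b1, b2))))
    stopf("isotherm parameters must be finite")
  if (any(b1 <= 0))
    stopf("'b1' must be > 0 (Henry coefficient positivity)")
  check_number(L1, "L1", lower = 0)
  check_number(kla, "kla", lower = 0, strict_lower = TRUE)
  if (length(cmod_range) != 2L || cmod_range[1] > cmod_range[2])
    stopf("'cmod_range' must be an increasing pair of modifier bounds")
  qmax_lo <- a1 * cmod_range[1] + a2
  qmax_hi <- a1 * cmod_range[2] + a2
  if (any(qmax_lo <= 0) || any(qmax_hi <= 0))
    stopf("qmax(cmod) = a1*cmod + a2 must stay > 0 over cmod_range [%g, %g]",
          cmod_range[1], cmod_range[2])
  if (is.null(component_names)) component_names <- paste0("comp", seq_len(n))
  structure(list(a1 = as.numeric(a1), a2 = as.numeric(a2),
                 b1 = as.numeric(b1), b2 = as.numeric(b2),
                 L1 = L1, kla = kla, cmod_range = as.numeric(cmod_range),
                 component_names = component_names),
            class = "mc_isotherm")
}

#' @export
print.mc_isotherm <- function(x, ...) {
  cat("Salt-dependent competitive Langmuir isotherm\n")
  tab <- data.frame(component = x$component_names, a1 = x$a1, a2 = x$a2,
                    b1 = x$b1, b2 = x$b2)
  print(tab, row.names = FALSE)
  cat(sprintf("  L1 = %g 1/M, kla = %g 1/min, valid cmod in [%g, %g] M\n",
              x$L1, x$kla, x$cmod_range[1], x$cmod_range[2]))
  invisible(x)
}

## vectorized equilibrium loading: c is a matrix (points x components),
## cmod a vector (one per point); returns a matrix of the same shape
qstar_matrix <- function(cmat, cmod, params) {
  n <- length(params$a2)
  qmax <- outer(cmod, params$a1) + rep(params$a2, each = length(cmod))
  H <- outer(cmod, seq_len(n),
             function(cm, j) params$b1[j] * cm^params$b2[j])
  denom <- 1 + rowSums(H / qmax * cmat)
  H * cmat / denom + params$L1 * cmod * cmat
}

#' Equilibrium membrane loading for a liquid composition
#'
#' Evaluates the salt-dependent competitive Langmuir isotherm.
#'
#' @param c numeric vector of liquid concentrations (g/L), one per binding
#'   component (all >= 0).
#' @param cmod modifier concentration, mol/L.
#' @param params an [isotherm_params()] object.
#' @return Numeric vector of equilibrium loadings q (g per L of membrane
#'   volume), one per component.
#' @export
q_equilibrium <- function(c, cmod, params) {
  if (!inherits(params, "mc_isotherm"))
    stopf("'params' must be an mc_isotherm object")
  n <- length(params$a2)
  if (length(c) != n)
    stopf("'c' must have %d entries (one per binding component)", n)
  if (any(!is.finite(c)) || any(c < 0))
    stopf("concentrations must be finite and >= 0")
  check_number(cmod, "cmod", lower = 0)
  qmax <- params$a1 * cmod + params$a2
  if (any(qmax <= 0))
    stopf("qmax(cmod) <= 0 at cmod = %g M; parameters are valid for cmod in [%g, %g] M",
          cmod, params$cmod_range[1], params$cmod_range[2])
  q <- qstar_matrix(matrix(c, nrow = 1L), cmod, params)
  stats::setNames(as.numeric(q), params$component_names)
}

#' Batch-adsorption data point
#'
#' One point of a static binding-capacity experiment: a membrane piece of
#' adsorptive volume `V_ads` equilibrated in `V_total` of liquid, with the
#' supernatant analyzed before binding (`c_feed`), after binding
#' (`c_star_binding`), and after elution into fresh buffer
#' (`c_star_elution`).
#'
#' @param c_feed,c_star_binding,c_star_elution numeric vectors (g/L, one
#'   entry per component).
#' @param V_total total liquid volume, mL.
#' @param V_ads adsorptive (membrane) volume, mL.
#' @param c_mod modifier concentration during binding, mol/L.
#' @param tolerance allowed relative excess of `c_star_binding` over
#'   `c_feed` (measurement noise).
#' @return An object of class `mc_batch_point`.
#' @export
batch_point <- function(c_feed, c_star_binding, c_star_elution,
                        V_total, V_ads, c_mod, tolerance = 0.05) {
  check_number(V_total, "V_total", lower = 0, strict_lower = TRUE)
  check_number(V_ads, "V_ads", lower = 0, strict_lower = TRUE)
  check_number(c_mod, "c_mod", lower = 0)
  conc <- c(c_feed, c_star_binding, c_star_elution)
  if (any(!is.finite(conc)) || any(conc < 0))
    stopf("all concentrations must be finite and >= 0")
  if (any(c_star_binding > c_feed * (1 + tolerance) + 1e-12))
    stopf("supernatant concentration after binding exceeds the feed beyond tolerance")
  structure(list(c_feed = c_feed, c_star_binding = c_star_binding,
                 c_star_elution = c_star_elution, V_total = V_total,
                 V_ads = V_ads, c_mod = c_mod),
            class = "mc_batch_point")
}

#' Membrane loading from the binding-step mass balance
#'
#' `q = (c_feed - c*) * V_total / V_ads`, the mass lost from the liquid per
#' adsorber volume.
#'
#' @param point a [batch_point()].
#' @param component component index (default: all components).
#' @param tolerance relative tolerance below zero before an error is raised
#'   (a clearly negative loading signals swapped samples).
#' @return Loading(s) q in g per L of membrane volume.
#' @export
loading_from_binding <- function(point, component = NULL, tolerance = 0.05) {
  if (!inherits(point, "mc_batch_point")) stopf("'point' must be a batch_point")
  i <- component %||% seq_along(point$c_feed)
  q <- (point$c_feed[i] - point$c_star_binding[i]) * point$V_total / point$V_ads
  floor_q <- -tolerance * point$c_feed[i] * point$V_total / point$V_ads
  if (any(q < pmin(floor_q, -1e-9)))
    stopf("binding mass balance gives a negative loading (%.3g); samples swapped?",
          min(q))
  pmax(q, 0)
}

#' Membrane loading from the elution-step mass balance
#'
#' `q = c* * V_total / V_ads`, the mass recovered into the elution buffer per
#' adsorber volume.  For a loss-free experiment it equals
#' [loading_from_binding()].
#'
#' @inheritParams loading_from_binding
#' @return Loading(s) q in g per L of membrane volume.
#' @export
loading_from_elution <- function(point, component = NULL) {
  if (!inherits(point, "mc_batch_point")) stopf("'point' must be a batch_point")
  i <- component %||% seq_along(point$c_star_elution)
  point$c_star_elution[i] * point$V_total / point$V_ads
}

#' Batch-adsorption dataset
#'
#' @param points list of [batch_point()] objects.
#' @param resin_label `"IEX"` or `"HIC"` (bookkeeping only).
#' @return An object of class `mc_isotherm_data`.
#' @export
isotherm_dataset <- function(points, resin_label = "IEX") {
  if (!length(points) || !all(vapply(points, inherits, logical(1),
                                     "mc_batch_point")))
    stopf("'points' must be a non-empty list of batch_point objects")
  structure(list(points = points, resin_label = resin_label),
            class = "mc_isotherm_data")
}

## flatten a dataset into (cmat, cmod, qmat) for fitting.  Loadings are the
## raw binding mass balances, deliberately NOT floored at zero: symmetric
## measurement noise must stay symmetric or the fit is biased.
dataset_design <- function(dataset) {
  cmat <- do.call(rbind, lapply(dataset$points, function(p) p$c_star_binding))
  cmod <- vapply(dataset$points, function(p) p$c_mod, numeric(1))
  qmat <- do.call(rbind, lapply(dataset$points, function(p)
    (p$c_feed - p$c_star_binding) * p$V_total / p$V_ads))
  list(cmat = cmat, cmod = cmod, qmat = qmat)
}

## pack/unpack the free parameter vector for the optimizer.
## b1 is fitted on the log scale (positivity); everything else raw.
pack_params <- function(a1, a2, b1, b2, L1, fit_L1) {
  p <- c(a1, a2, log(b1), b2)
  if (fit_L1) p <- c(p, L1)
  p
}
unpack_params <- function(p, n, fit_L1, L1_fixed = 0) {
  list(a1 = p[seq_len(n)],
       a2 = p[n + seq_len(n)],
       b1 = exp(p[2L * n + seq_len(n)]),
       b2 = p[3L * n + seq_len(n)],
       L1 = if (fit_L1) max(p[4L * n + 1L], 0) else L1_fixed)
}

## model residuals (+ soft penalty keeping qmax positive over the data range)
isotherm_residuals <- function(p, design, n, fit_L1, L1_fixed) {
  u <- unpack_params(p, n, fit_L1, L1_fixed)
  cmod <- design$cmod
  qmax <- outer(cmod, u$a1) + rep(u$a2, each = length(cmod))
  pen <- pmax(1e-3 - qmax, 0) * 1e4
  qmax_safe <- pmax(qmax, 1e-3)
  H <- outer(cmod, seq_len(n), function(cm, j) u$b1[j] * cm^u$b2[j])
  denom <- 1 + rowSums(H / qmax_safe * design$cmat)
  qhat <- H * design$cmat / denom + u$L1 * cmod * design$cmat
  c(as.numeric(qhat - design$qmat), as.numeric(pen))
}

## single-component Langmuir estimates per modifier level -> regression on
## cmod gives a deterministic starting point for the joint fit
isotherm_heuristic_start <- function(design, n) {
  cmod_levels <- sort(unique(design$cmod))
  Hl <- matrix(NA_real_, length(cmod_levels), n)
  ql <- matrix(NA_real_, length(cmod_levels), n)
  for (k in seq_along(cmod_levels)) {
    sel <- design$cmod == cmod_levels[k]
    for (j in seq_len(n)) {
      cc <- design$cmat[sel, j]
      qq <- design$qmat[sel, j]
      ok <- cc > 0 & qq > 0
      if (sum(ok) >= 2L) {
        ## linearized Langmuir: c/q = 1/H + c/qmax
        fitlm <- stats::lm(I(cc[ok] / qq[ok]) ~ cc[ok])
        H0 <- 1 / max(stats::coef(fitlm)[1], 1e-8)
        qm0 <- 1 / max(stats::coef(fitlm)[2], 1e-8)
        Hl[k, j] <- max(H0, 1e-6)
        ql[k, j] <- min(max(qm0, max(qq)), 1e6)
      }
    }
  }
  a1 <- a2 <- b1 <- b2 <- numeric(n)
  for (j in seq_len(n)) {
    ok <- is.finite(ql[, j])
    if (sum(ok) >= 2L) {
      cf <- stats::coef(stats::lm(ql[ok, j] ~ cmod_levels[ok]))
      a1[j] <- cf[2]; a2[j] <- max(cf[1], 1)
    } else {
      a1[j] <- 0; a2[j] <- max(design$qmat[, j], 1)
    }
    ok <- is.finite(Hl[, j]) & cmod_levels > 0
    if (sum(ok) >= 2L) {
      cf <- stats::coef(stats::lm(log(Hl[ok, j]) ~ log(cmod_levels[ok])))
      b1[j] <- exp(cf[1]); b2[j] <- cf[2]
    } else {
      b1[j] <- max(stats::median(Hl[, j], na.rm = TRUE), 1, na.rm = TRUE)
      b2[j] <- 0
    }
  }
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
}

#' Fit salt-dependent competitive Langmuir parameters to batch data
#'
#' Minimizes the least-squares error between measured loadings (from the
#' binding mass balance) and the competitive Langmuir model over all points
#' and components.  Because the Henry power law in the modifier creates
#' local minima, the Levenberg-Marquardt refinement is run from a
#' deterministic linearized-Langmuir starting point plus `n_starts - 1`
#' jittered restarts (fixed seed), and the best solution is kept.
#'
#' @param dataset an [isotherm_dataset()] spanning at least two modifier
#'   levels and two concentration levels.
#' @param n_components number of binding components (defaults to the number
#'   of concentration columns in the data).
#' @param fit_L1 fit the linear HIC term? If `FALSE`, `L1` is fixed at
#'   `L1_fixed` (ion exchange).
#' @param L1_fixed value of `L1` when not fitted.
#' @param kla kinetic coefficient (1/min) carried into the returned
#'   parameter object (batch equilibration does not inform it).
#' @param n_starts number of multi-starts (>= 1).
#' @param seed integer seed for the jittered restarts.
#' @return An object of class `mc_isotherm_fit` with components `params`
#'   (an [isotherm_params()] object), `residuals`, `fitted`, `observed`,
#'   `rss` and `convergence`.
#' @export
fit_isotherm <- function(dataset, n_components = NULL, fit_L1 = FALSE,
                         L1_fixed = 0, kla = 6, n_starts = 5L, seed = 1L) {
  if (!inherits(dataset, "mc_isotherm_data"))
    stopf("'dataset' must be an isotherm_dataset")
  design <- dataset_design(dataset)
  n <- n_components %||% ncol(design$cmat)
  if (ncol(design$cmat) != n)
    stopf("dataset has %d components, n_components = %d", ncol(design$cmat), n)
  n_levels <- length(unique(design$cmod))
  if (n_levels < 2L)
    stopf(paste("only %d modifier level(s): the salt dependence (b-parameters)",
                "is unidentifiable; fix b2 or add modifier levels"), n_levels)
  start <- isotherm_heuristic_start(design, n)
  p0 <- pack_params(start$a1, start$a2, start$b1, start$b2, 1e-3, fit_L1)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(max(1L, n_starts))) {
    p_init <- if (s == 1L) p0 else
      p0 * stats::runif(length(p0), 0.6, 1.4) +
        stats::rnorm(length(p0), 0, 0.05)
    fit <- try(minpack.lm::nls.lm(
      par = p_init, fn = isotherm_residuals, design = design, n = n,
      fit_L1 = fit_L1, L1_fixed = L1_fixed,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stopf("isotherm fit failed from every start")
  u <- unpack_params(best$fit$par, n, fit_L1, L1_fixed)
  cmod_range <- range(design$cmod)
  params <- isotherm_params(u$a1, u$a2, u$b1, u$b2, L1 = u$L1, kla = kla,
                            cmod_range = cmod_range,
                            component_names = colnames(design$cmat) %||%
                              paste0("comp", seq_len(n)))
  qhat <- qstar_matrix(design$cmat, design$cmod, params)
  res <- design$qmat - qhat
  structure(list(params = params, observed = design$qmat, fitted = qhat,
                 residuals = res, rss = sum(res^2),
                 n_points = nrow(design$cmat), n_components = n,
                 convergence = best$fit$info, dataset = dataset),
            class = "mc_isotherm_fit")
}

#' @export
print.mc_isotherm_fit <- function(x, ...) {
  cat(sprintf("Competitive Langmuir fit: %d points, %d components, RSS = %.4g\n",
              x$n_points, x$n_components, x$rss))
  print(x$params)
  invisible(x)
}

#' @export
coef.mc_isotherm_fit <- function(object, ...) {
  p <- object$params
  out <- c(stats::setNames(p$a1, paste0("a1.", p$component_names)),
           stats::setNames(p$a2, paste0("a2.", p$component_names)),
           stats::setNames(p$b1, paste0("b1.", p$component_names)),
           stats::setNames(p$b2, paste0("b2.", p$component_names)),
           L1 = p$L1)
  out
}

#' @export
residuals.mc_isotherm_fit <- function(object, ...) object$residuals

#' Predict equilibrium loadings from a fitted isotherm
#'
#' @param object an `mc_isotherm_fit`.
#' @param newdata list with elements `c` (matrix, points x components) and
#'   `cmod` (vector); defaults to the training design.
#' @param ... unused.
#' @return Matrix of predicted loadings (g/L-membrane).
#' @export
predict.mc_isotherm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  cmat <- as.matrix(newdata$c)
  qstar_matrix(cmat, newdata$cmod, object$params)
}

#' @export
plot.mc_isotherm_fit <- function(x, ...) {
  graphics::plot(as.numeric(x$observed), as.numeric(x$fitted),
                 xlab = "measured q (g/L membrane)",
                 ylab = "fitted q (g/L membrane)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
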