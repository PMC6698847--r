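test_that("moments match analytic values for simple shapes", {
  ## symmetric triangle centered at 10 min
  t <- seq(5, 15, by = 0.01)
  s <- pmax(1 - abs(t - 10) / 5, 0)
  m <- moments(tracer_curve(t, s, flow = 1), baseline_fraction = 0)
  expect_equal(m$t_mean, 10, tolerance = 1e-6)

  ## single-point spike degenerates to a Dirac
  m1 <- moments(tracer_curve(4, 1, flow = 1))
  expect_equal(m1$t_mean, 4)
  expect_equal(m1$variance, 0)

  ## exponential decay: closed-form moments of the exponential distribution
  t <- seq(0, 40, by = 0.002)
  m2 <- moments(tracer_curve(t, exp(-t / 2), flow = 1),
                baseline_fraction = 0)
  expect_equal(m2$t_mean, 2, tolerance = 1e-3)
  expect_equal(m2$variance, 4, tolerance = 1e-3)

  expect_error(moments(tracer_curve(c(1, 2), c(0, 0), flow = 1)),
               "zero area")
})

test_that("voidage follows the residence-volume balance", {
  expect_equal(voidage(3, 1, 1, 2.5), 0.8)
  expect_equal(voidage(2, 2, 5, 3), 0)
  expect_error(voidage(1, 2, 1, 3), "blank run")
})

test_that("closed-vessel dispersion inversion matches forward evaluation", {
  ## forward Eq. at x = 0.1: 2(0.1) - 2(0.01)(1 - e^-10) = 0.1800009
  nv <- 2 * 0.1 - 2 * 0.01 * (1 - exp(-10))
  expect_equal(nv, 0.1800009, tolerance = 1e-7)
  expect_equal(dax_from_variance_closed(nv, 1, 1), 0.1, tolerance = 1e-9)
  ## plug-flow limit
  expect_lt(dax_from_variance_closed(1e-8, 1, 1), 1e-8)
  expect_error(dax_from_variance_closed(1.2, 1, 1), "\\(0, 1\\)")
  expect_error(dax_from_variance_closed(0, 1, 1), "\\(0, 1\\)")
})

test_that("open-vessel inversion is the closed-form positive root", {
  ## forward: 2(0.1) + 8(0.01) = 0.28
  expect_equal(dax_from_variance_open(0.28, 1, 1), 0.1, tolerance = 1e-12)
  expect_equal(dax_from_variance_open(1e-12, 1, 1), 0, tolerance = 1e-12)
})

test_that("inversion round trips hold across the physical x range", {
  forward_closed <- function(x) 2 * x - 2 * x^2 * (1 - exp(-1 / x))
  forward_open <- function(x) 2 * x + 8 * x^2
  for (x in 10^seq(-4, log10(9), length.out = 25)) {
    if (forward_closed(x) < 1) {
      xc <- dax_from_variance_closed(forward_closed(x), 2, 3) / 6
      expect_equal(xc, x, tolerance = 1e-9)
    }
    xo <- dax_from_variance_open(forward_open(x), 2, 3) / 6
    expect_equal(xo, x, tolerance = 1e-9)
  }
  ## in the small-dispersion regime the two boundary-condition variants
  ## nearly coincide: series expansion gives a relative gap of 5x = 2.5 nv
  ## to leading order, so the gap vanishes linearly in nv
  for (x in c(1e-3, 0.01, 0.05)) {
    nv <- forward_closed(x)
    gap <- abs(dax_from_variance_open(nv, 1, 1) - x) / x
    expect_lt(gap, 3 * nv + 1e-9)
  }
})

test_that("Bodenstein numbers and regime classification", {
  expect_equal(bodenstein(1, 1, 1), 1)
  expect_equal(bodenstein(1, 1, 250), 0.004)
  expect_equal(classify_regime(3), "stirred_tank")
  expect_equal(classify_regime(30), "plug_flow")
})

test_that("tracer_fit recovers voidage and a consistent dispersion pair", {
  cv <- make_tracer_curve(test_spec(), flow = 1)
  fit <- tracer_fit(cv, t_instrument = attr(cv, "t_instrument"),
                    Vm = 3, l = 0.8)
  expect_equal(fit$voidage, 0.8, tolerance = 1e-3)
  expect_gt(fit$Dax_closed, 0)
  expect_gt(fit$Dax_open, 0)
  ## both estimates describe the same curve; open >= closed is the usual
  ## ordering at large normalized variance
  expect_gt(fit$Bo_closed, 0)
})
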