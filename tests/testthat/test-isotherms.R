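test_that("batch mass balances give the textbook loadings", {
  p <- batch_point(c_feed = 5, c_star_binding = 1, c_star_elution = 1,
                   V_total = 5, V_ads = 0.05, c_mod = 0.02)
  expect_equal(unname(loading_from_binding(p)), 400)
  expect_equal(unname(loading_from_elution(p)), 100)
  p0 <- batch_point(5, 5, 0, 5, 0.05, 0.02)
  expect_equal(unname(loading_from_binding(p0)), 0)
  expect_equal(unname(loading_from_elution(p0)), 0)
  ## clearly negative loading signals swapped samples
  p_bad <- batch_point(1, 2, 0, 5, 0.05, 0.02, tolerance = 1.5)
  expect_error(loading_from_binding(p_bad, tolerance = 0.05), "swapped")
})

test_that("equilibrium loading matches hand evaluation and limits", {
  ## single component, H = 10, qmax = 100: q = 10*1/(1 + 10/100) = 9.0909..
  p <- isotherm_params(a1 = 0, a2 = 100, b1 = 10, b2 = 0, L1 = 0)
  expect_equal(unname(q_equilibrium(1, 0.1, p)), 10 / 1.1,
               tolerance = 1e-12)
  expect_equal(unname(q_equilibrium(0, 0.1, p)), 0)
  ## saturation limit q -> qmax as c -> infinity
  expect_equal(unname(q_equilibrium(1e7, 0.1, p)), 100, tolerance = 1e-4)
  ## qmax(cmod) <= 0 outside the validity range is an error
  p2 <- isotherm_params(a1 = -100, a2 = 50, b1 = 1, b2 = 0,
                        cmod_range = c(0, 0.4))
  expect_error(q_equilibrium(1, 0.9, p2), "valid for cmod")
})

test_that("equilibrium is monotone in own concentration and competitive", {
  p <- synthetic_iex_isotherm()
  cmod <- 0.05
  grid <- seq(0, 10, by = 0.5)
  q_own <- vapply(grid, function(c1)
    q_equilibrium(c(c1, 0.5, 0.5), cmod, p)[1], numeric(1))
  expect_true(all(diff(q_own) > -1e-12))
  ## raising a competitor never raises q_i when L1 = 0
  q_comp <- vapply(grid, function(c3)
    q_equilibrium(c(2, 0.5, c3), cmod, p)[1], numeric(1))
  expect_true(all(diff(q_comp) < 1e-12))
})

test_that("generator equilibria close the batch mass balances", {
  ds <- make_isotherm_dataset(test_spec(), modifier_levels = c(0.02, 0.1),
                              feed_fractions = c(0.5, 1))
  tr <- attr(ds, "truth")
  for (pt in ds$points) {
    qb <- loading_from_binding(pt)
    qe <- loading_from_elution(pt)
    ## loss-free generator: both balances agree exactly
    expect_equal(qb, qe, tolerance = 1e-9)
    ## and reproduce the generating equilibrium loading
    qm <- q_equilibrium(pt$c_star_binding, pt$c_mod, tr)
    expect_equal(unname(qb), unname(qm), tolerance = 1e-7)
  }
})

test_that("noise-free fitting recovers the generating parameters", {
  ds <- make_isotherm_dataset(test_spec(), feed_conc = ratio_varied_feeds(),
                              V_ads = 1)
  fit <- fit_isotherm(ds, fit_L1 = FALSE)
  tr <- attr(ds, "truth")
  for (f in c("a1", "a2", "b1", "b2"))
    expect_equal(fit$params[[f]], tr[[f]], tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("fit is invariant to the ordering of data points", {
  ds <- make_isotherm_dataset(test_spec(),
                              modifier_levels = c(0.02, 0.05, 0.1, 0.2),
                              feed_conc = ratio_varied_feeds()[1:4, ],
                              V_ads = 1)
  set.seed(42)
  ds_shuffled <- isotherm_dataset(sample(ds$points), ds$resin_label)
  f1 <- fit_isotherm(ds)
  f2 <- fit_isotherm(ds_shuffled)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("single modifier level is rejected as rank-deficient", {
  ds <- make_isotherm_dataset(test_spec(), modifier_levels = 0.1)
  expect_error(fit_isotherm(ds), "unidentifiable|fix b2")
})

test_that("the linear HIC term improves a HIC-generated fit", {
  sp <- test_spec(isotherm = synthetic_hic_isotherm())
  ds <- make_isotherm_dataset(sp,
                              modifier_levels = c(0.2, 0.5, 0.6, 0.8, 1),
                              feed_conc = ratio_varied_feeds()[1:4, ],
                              V_ads = 1, resin_label = "HIC")
  fit_free <- fit_isotherm(ds, fit_L1 = TRUE)
  fit_fixed <- fit_isotherm(ds, fit_L1 = FALSE)
  expect_lt(fit_free$rss, fit_fixed$rss)
})

test_that("fit object methods are coherent", {
  ds <- make_isotherm_dataset(test_spec(),
                              modifier_levels = c(0.02, 0.05, 0.1, 0.2),
                              feed_conc = ratio_varied_feeds()[1:4, ],
                              V_ads = 1)
  fit <- fit_isotherm(ds)
  expect_named(coef(fit)["L1"])
  expect_equal(dim(residuals(fit)), dim(fit$observed))
  pr <- predict(fit, newdata = list(c = matrix(c(1, 0.1, 0.1), 1),
                                    cmod = 0.05))
  expect_equal(unname(as.numeric(pr)),
               unname(q_equilibrium(c(1, 0.1, 0.1), 0.05, fit$params)),
               tolerance = 1e-12)
  expect_output(print(fit), "Competitive Langmuir fit")
})
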