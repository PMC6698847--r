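spec20 <- case_study_spec(20, 5, module_volume = 5, batch_runs = 3,
                          module_volume_seq = 0.15)
spec200 <- case_study_spec(200, 5, module_volume = 5, batch_runs = 30)
spec2000 <- case_study_spec(2000, 5, module_volume = 5, batch_runs = 300)

test_that("pressure model reproduces the module-train backpressure", {
  pm <- pressure_model(per_module_coefficient = 0.2,
                       instrument_offset = 1.1, limit = 4)
  expect_equal(pressure_drop(3, 4, pm, include_offset = FALSE)$pressure,
               2.4)
  pr <- pressure_drop(3, 4, pm)
  expect_equal(pr$pressure, 3.5)
  expect_true(pr$within_limit)
  expect_equal(pressure_drop(0, 4, pm)$pressure, 1.1)
})

test_that("batch capacity is scale-invariant arithmetic", {
  expect_equal(batch_capacity(spec20), 20 * 5 / (3 * 5))
  expect_equal(batch_capacity(spec2000), batch_capacity(spec20))
  sp0 <- spec20; sp0$titer <- 1e-12
  expect_equal(batch_capacity(sp0), 1e-12 * 20 / 15)
})

test_that("cycle times decompose into loading and protocol blocks", {
  expect_equal(cycle_time(20 / 3, 5, 5, 15, 5), 20 / 15 / 5 + 3,
               tolerance = 1e-12)
  expect_equal(cycle_time(11.4, 5, 3, 15, 5), 0.76 + 3)
  expect_equal(cycle_time(10, 5, 4, 0, 5), 0.5)
})

test_that("productivity and eluent consumption follow their definitions", {
  cap_b <- batch_capacity(spec20)
  ct_b <- cycle_time(cap_b, 5, 5, 15, 5)
  expect_equal(productivity_per_cycle(cap_b, ct_b), 2939, tolerance = 1e-3)
  expect_equal(productivity_per_cycle(0, 3), 0)
  expect_equal(eluent_consumption(cap_b, 5, 15), 2.45, tolerance = 1e-3)
  ## limiting case: no protocol buffer, capacity = titer over 1 CV
  expect_equal(eluent_consumption(5, 5, 0), 1 / 5)
  ## buffer-only accounting variant
  expect_equal(eluent_consumption(cap_b, 5, 15, buffer_only = TRUE),
               15 / cap_b)
})

test_that("sequential sizing reproduces rounded volumes and cycle counts", {
  sz2000 <- size_sequential(spec2000)
  expect_equal(sz2000$total_membrane_volume, 877)
  expect_equal(sz2000$n_cycles, 44)
  expect_equal(size_sequential(spec200)$total_membrane_volume, 88)
  sz20 <- size_sequential(spec20)
  expect_equal(sz20$total_membrane_volume, 8.8)  # < 10 L: 0.1 L rounding
  expect_equal(sz20$n_cycles, 15)                # 0.15 L modules, 4 in line
  sp1 <- spec2000; sp1$capacity_gain_factor <- 1
  expect_equal(size_sequential(sp1)$total_membrane_volume, 1500)
})

test_that("batch runtimes accumulate per-run cycle times", {
  expect_equal(batch_runtime(spec20), 0.1633, tolerance = 1e-3)
  expect_equal(batch_runtime(spec200), 1.6333, tolerance = 1e-3)
  expect_equal(batch_runtime(spec2000), 16.3333, tolerance = 1e-3)
})

test_that("module volume cancels out of the intensive metrics", {
  for (mv in c(0.003, 0.15, 5)) {
    sp <- case_study_spec(2000, 5, module_volume = mv,
                          batch_runs = 300 * 5 / mv)
    cap <- batch_capacity(sp)
    expect_equal(productivity_per_cycle(cap,
                                        cycle_time(cap, 5, 5, 15, 5)),
                 2939, tolerance = 1e-3)
    expect_equal(eluent_consumption(cap, 5, 15), 2.45, tolerance = 1e-3)
  }
})

test_that("eluent consumption decreases and productivity increases in capacity", {
  caps <- seq(2, 30, by = 2)
  ec <- vapply(caps, eluent_consumption, numeric(1), titer = 5,
               elution_cv = 15)
  expect_true(all(diff(ec) < 0))
  pr <- vapply(caps, function(cp)
    productivity_per_cycle(cp, cycle_time(cp, 5, 3, 15, 5)), numeric(1))
  expect_true(all(diff(pr) > 0))
})

test_that("comparison deltas are consistent and antisymmetric", {
  b <- performance_report(spec2000, "batch")
  s <- performance_report(spec2000, "sequential")
  d <- compare_performance(b, s)
  expect_equal(d$capacity, 71, tolerance = 1e-9)
  expect_equal(d$productivity, 48.56, tolerance = 1e-2)
  expect_equal(d$eluent, -38.1, tolerance = 0.05)
  d0 <- compare_performance(b, b)
  expect_equal(unlist(d0), c(capacity = 0, productivity = 0, eluent = 0,
                             runtime = 0))
  ## antisymmetry on the log/relative scale
  d_rev <- compare_performance(s, b)
  expect_equal((1 + d$productivity / 100) * (1 + d_rev$productivity / 100),
               1, tolerance = 1e-12)
})
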