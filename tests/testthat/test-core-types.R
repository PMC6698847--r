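test_that("CV-to-volume conversion is exact multiplication", {
  g5000 <- module_geometry(Vm = 5000)
  g150 <- module_geometry(Vm = 150)
  expect_equal(cv_to_volume(3, g5000), 15000)
  expect_equal(cv_to_volume(0, g5000), 0)
  expect_equal(cv_to_volume(15, g150), 2250)
  expect_error(cv_to_volume(-1, g150), "finite and >= 0")
})

test_that("geometry invariants are enforced and porosity is derived", {
  g <- nano_geometry()
  expect_equal(g$Vm, 3)
  expect_equal(g$eps, 0.8)
  expect_equal(sum(g$zone_volumes[c(1, 2, 4, 5)]) + g$eps_mem * g$Vm,
               g$eps * g$Vm)
  expect_error(module_geometry(Vm = -1), "outside the admissible range")
  expect_error(module_geometry(Vm = 3, eps = 1.2), "outside the admissible")
  expect_error(module_geometry(Vm = 3, zone_volumes = c(1, 1, 1, -1)),
               "positive")
})

test_that("component systems enforce unique ids and one modifier", {
  cs <- component_system(list(component(1, "a", "product"),
                              component(2, "b", "modifier")), c(1, 0))
  expect_s3_class(cs, "mc_component_system")
  expect_error(component_system(list(component(1, "a", "product"),
                                     component(1, "b", "tracer")), c(1, 0)),
               "unique")
  expect_error(component_system(list(component(1, "a", "modifier"),
                                     component(2, "b", "modifier")), c(0, 0)),
               "modifier")
  expect_error(component_system(list(component(1, "a", "product")), -1),
               ">= 0")
})

test_that("schedules require unique step names and positive durations", {
  s1 <- operating_step("load", 2, 5, inlet = c(x = 1))
  expect_error(operating_step("load", -2, 5), "outside the admissible")
  expect_error(process_schedule(s1, s1), "unique")
  sched <- process_schedule(s1, operating_step("wash", 3, 5))
  expect_length(sched$steps, 2L)
})

test_that("config validation injects documented defaults and flags errors", {
  cfg <- validate_config(list(geometry = list(Vm = 3)))
  expect_equal(cfg$geometry$eps, 0.8)
  expect_equal(cfg$fluidics$Dax, c(9e-4, 9e-4, 5e-3, 250, 250))
  expect_error(validate_config(list(geometry = list(bed_height = 8))),
               "Vm")
  expect_error(validate_config(list(geometry = list(Vm = 3, eps = 1.2))),
               "outside the admissible")
  ## explicit dispersion values are echoed back unchanged
  cfg2 <- validate_config(list(geometry = list(Vm = 3),
                               fluidics = list(Dax = c(1, 2, 3, 4, 5))))
  expect_equal(cfg2$fluidics$Dax, c(1, 2, 3, 4, 5))
})

test_that("config serialization round trips", {
  raw <- list(geometry = list(Vm = 3, eps = 0.75),
              fluidics = list(Dax = c(1e-3, 1e-3, 5e-3, 100, 100)),
              components = list(
                list(id = 1, name = "product", role = "product", feed = 5),
                list(id = 2, name = "modifier", role = "modifier")),
              schedule = list(list(name = "load", duration_cv = 2,
                                   flow_cv = 5,
                                   inlet = list(product = 5))),
              case_study = list(fermenter_volume = 2000, titer = 5,
                                module_volume = 5, batch_runs = 300))
  cfg <- validate_config(raw)
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$geometry, cfg$geometry)
  expect_equal(cfg2$fluidics, cfg$fluidics)
  expect_equal(cfg2$system, cfg$system)
  expect_equal(cfg2$case_study, cfg$case_study)
  expect_equal(length(cfg2$schedule$steps), 1L)
})
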