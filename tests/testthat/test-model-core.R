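test_that("transit rates follow (n+1)/MMT", {
  expect_equal(transit_rate(6.1, 3), 4 / 6.1, tolerance = 1e-12)
  expect_equal(round(transit_rate(6.1, 3), 5), 0.65574)
  expect_equal(round(transit_rate(7.0, 3), 5), 0.57143)
  expect_equal(transit_rate(4.0, 3), 1.0)
  expect_error(transit_rate(0, 3), "positive")
  expect_error(transit_rate(-1, 3), "positive")
  expect_error(transit_rate(6.1, 0), ">= 1")
})

test_that("conditioning drug effect is rho on the closed window, 0 outside", {
  reg <- treatment_regimen(-6, -2)
  expect_equal(drug_effect(-4, reg, 0.945), 0.945)
  expect_equal(drug_effect(c(-6, -2), reg, 0.945), c(0.945, 0.945))
  expect_equal(drug_effect(-10, reg, 0.945), 0)
  expect_equal(drug_effect(3, reg, 0.945), 0)
  expect_equal(drug_effect(-1.999, reg, 0.945), 0)
})

test_that("the pre-HCT baseline initializes a patient-chain steady state", {
  pop <- population_parameters()
  y <- initialize_state(pop)
  expect_equal(unname(y[c("HSC_PAT", "TR1_PAT", "TR2_PAT", "TR3_PAT",
                          "PLT_PAT")]),
               rep(90.5, 5))
  expect_equal(unname(y[6:14]), rep(0, 9))
  y1 <- initialize_state(realize_parameters(
    population_parameters(baseline_plt_pat = 1)))
  expect_equal(unname(y1[1:5]), rep(1, 5))
  # steady state by construction: zero derivative without drug or graft
  d <- derivatives(-10, y, pop, treatment_regimen())
  expect_equal(unname(d), rep(0, 14), tolerance = 1e-12)
})

test_that("derivatives reproduce hand-computed rates and reject bad input", {
  pop <- population_parameters()
  reg <- treatment_regimen()
  y <- initialize_state(pop)
  # an empty graft stays empty
  d <- derivatives(5, y, pop, reg)
  expect_equal(unname(d[8:14]), rep(0, 7))
  # first-order HCT-effect decline at the published magnitude
  y2 <- y; y2[["HCT"]] <- 4.22
  d2 <- derivatives(5, y2, pop, reg)
  expect_equal(unname(d2[["HCT"]]), -0.353 * 4.22, tolerance = 1e-12)
  expect_equal(round(unname(d2[["HCT"]]), 4), -1.4897)
  # conditioning inhibits HSC proliferation by rho
  d3 <- derivatives(-4, y, pop, reg)
  expect_equal(unname(d3[["HSC_PAT"]]), -transit_rate(6.1, 3) * 0.945 * 90.5,
               tolerance = 1e-12)
  expect_error(derivatives(0, y - 1, pop, reg), "non-negative")
  y_bad <- y; y_bad[1] <- NaN
  expect_error(derivatives(0, y_bad, pop, reg), "finite")
})

test_that("the bolus schedule carries graft, HCT, day-1 and transfusion inputs", {
  pop <- population_parameters()
  ev <- event_schedule(pop, treatment_regimen(donor_relation = "related"))
  expect_equal(ev$amount[ev$compartment == "PLT_PAT"], 20.1 * 2.75)
  expect_equal(ev$amount[ev$compartment == "Graft1"], 72.4)
  expect_equal(ev$amount[ev$compartment == "HCT"], 4.22)
  expect_true(all(ev$time == 0))

  ev2 <- event_schedule(pop, treatment_regimen(donor_relation = "unrelated"))
  expect_equal(ev2$amount[ev2$compartment == "PLT_PAT"], 20.1)

  reg3 <- treatment_regimen(transfusion_times = c(4, 9))
  ev3 <- event_schedule(pop, reg3)
  expect_equal(ev3$amount[ev3$type == "transfusion"], c(10.6, 10.6))
  expect_equal(ev3$time[ev3$type == "transfusion"], c(4, 9))

  reg4 <- atg_regimen()
  ev4 <- event_schedule(pop, reg4)
  expect_equal(ev4$time[ev4$type == "atg"], c(-4, -3, -2))
  expect_equal(ev4$amount[ev4$type == "atg"], rep(800, 3))

  # events before the simulation start are rejected
  expect_error(simulate_individual(pop, reg4, grid = seq(-3, 40, 0.25)),
               "before the simulation start")
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  pop <- population_parameters()
  reg <- atg_regimen(transfusion_times = c(3, 6))
  cov <- covariate_series(c(-5, 2, 9), c(5.0, 4.6, 6.1))
  g <- seq(-30, 50, 0.5)
  a <- simulate_individual(pop, reg, cov, grid = g)
  b <- simulate_individual(pop, reg, cov, grid = g,
                           control = sim_control(use_compiled = FALSE))
  expect_equal(a$plt_total, b$plt_total, tolerance = 1e-5)
  expect_equal(a$plt_gt, b$plt_gt, tolerance = 1e-5)
})
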