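test_that("a clearance-free model conserves the administered dose", {
  phys <- load_physiology("monkey")
  kps <- setNames(rep(0.5, 14), phys$tissues$tissue)
  mod <- build_model(phys, kps, clearance = 0)
  sim <- simulate_pbpk(mod, t_end = 4, dosing = list(dose_event(10)))
  total <- rowSums(sim$amounts) + sim$eliminated
  expect_true(all(abs(total - 10) / 10 < 1e-6))
  expect_true(all(sim$amounts >= -1e-9))
})

test_that("model construction audits its inputs", {
  phys <- load_physiology("monkey")
  kps <- setNames(rep(0.5, 14), phys$tissues$tissue)
  expect_error(build_model(phys, kps[names(kps) != "spleen"], 1), "spleen")
  expect_error(build_model(phys, kps, -1), "clearance")
  bad_phys <- phys
  bad_phys$tissues$volume_L[1] <- 0
  expect_error(build_model(bad_phys, kps, 1), "validation")
})

test_that("mass balance holds to 1e-6 across random models", {
  for (seed in 1:5) {
    mod <- random_model(seed)
    dose <- runif(1, 1, 500)
    sim <- simulate_pbpk(mod, t_end = 6, dosing = list(dose_event(dose)))
    expect_lt(sim$mass_balance_error, 1e-6)
    expect_true(all(sim$amounts >= -1e-9 * dose))
  }
})

test_that("outputs superpose linearly in dose", {
  mod <- random_model(11)
  s1 <- simulate_pbpk(mod, 6, dosing = list(dose_event(5)))
  s4 <- simulate_pbpk(mod, 6, dosing = list(dose_event(20)))
  keep <- s1$conc_plasma > 0
  expect_true(all(abs(s4$conc_plasma[keep] / s1$conc_plasma[keep] - 4)
                  < 1e-6 * 4))
  a1 <- exposure_metrics(s1)$auc_last
  a4 <- exposure_metrics(s4)$auc_last
  expect_equal(a4 / a1, 4, tolerance = 1e-6)
})

test_that("AUCinf x CL / dose is unity for linear clearance", {
  for (seed in c(3, 7, 21)) {
    mod <- random_model(seed, cl_range = c(0.3, 2))
    dose <- 50
    sim <- simulate_until_eliminated(mod, dosing = list(dose_event(dose)),
                                     t_start = 24)
    auc <- exposure_metrics(sim)$auc_inf
    expect_equal(auc * mod$clearance / dose, 1, tolerance = 0.005)
  }
})

test_that("the solution is converged at the default tolerances", {
  phys <- load_physiology("monkey")
  mod <- build_model(phys, default_kps(), 0.6)
  s1 <- simulate_until_eliminated(mod, dosing = list(dose_event(69)),
                                  t_start = 24)
  s2 <- simulate_until_eliminated(mod, dosing = list(dose_event(69)),
                                  t_start = 24, rtol = 1e-9, atol = 1e-11)
  a1 <- exposure_metrics(s1)$auc_inf
  a2 <- exposure_metrics(s2)$auc_inf
  expect_lt(abs(a1 - a2) / a2, 0.001)
})

test_that("an infusion delivers its dose and obeys AUC = dose/CL", {
  mod <- random_model(5)
  inf <- dose_event(40, route = "iv_infusion", start_h = 0, duration_h = 1)
  sim <- simulate_until_eliminated(mod, dosing = list(inf), t_start = 24)
  expect_lt(sim$mass_balance_error, 1e-6)
  auc <- exposure_metrics(sim)$auc_inf
  expect_equal(auc * mod$clearance / 40, 1, tolerance = 0.005)
})

test_that("exposure metrics match closed forms", {
  t <- seq(0, 24, by = 0.01)
  mono <- structure(list(time = t, conc_plasma = 100 * exp(-0.6931 * t)),
                    class = "simulation_result")
  em <- exposure_metrics(mono)
  expect_equal(em$auc_inf, 100 / 0.6931, tolerance = 0.001)
  expect_equal(em$cmax, 100)
  expect_equal(em$tmax, 0)

  flat <- structure(list(time = seq(0, 1, 0.01),
                         conc_plasma = rep(10, 101)),
                    class = "simulation_result")
  expect_equal(exposure_metrics(flat, extrapolate = FALSE)$auc_last, 10)

  bad <- structure(list(time = c(0, 1, 0.5), conc_plasma = c(1, 2, 3)),
                   class = "simulation_result")
  expect_error(exposure_metrics(bad), "non-monotone")
})

test_that("dose events are validated", {
  expect_error(dose_event(0), "amount")
  expect_error(dose_event(10, duration_h = 1), "duration 0")
  expect_error(dose_event(10, route = "iv_infusion"), "duration")
})
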