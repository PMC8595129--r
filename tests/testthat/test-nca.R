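test_that("terminal slope recovers a mono-exponential decline", {
  t <- monkey_schedule()
  lam <- estimate_lambda_z(t, 100 * exp(-0.6931 * t))
  expect_equal(lam$lambda_z, 0.6931, tolerance = 0.001)
  expect_equal(log(2) / lam$lambda_z, 1.00, tolerance = 0.001)
  expect_gte(lam$n_points, 3)
})

test_that("non-declining profiles are flagged not estimable", {
  t <- 1:6
  lam <- estimate_lambda_z(t, c(1, 2, 4, 8, 16, 32))
  expect_true(is.na(lam$lambda_z))
  expect_match(lam$reason, "post-Tmax|declining")
  expect_true(is.na(estimate_lambda_z(c(1, 2), c(5, 3))$lambda_z))
})

test_that("terminal dominance isolates the slow phase of a bi-exponential", {
  t <- seq(0.1, 24, by = 0.1)
  conc <- 90 * exp(-3 * t) + 10 * exp(-0.3 * t)
  lam <- estimate_lambda_z(t, conc)
  expect_equal(lam$lambda_z, 0.3, tolerance = 0.02)
})

test_that("NCA matches closed forms on mono-exponential input", {
  t <- monkey_schedule()
  p <- conc_time_profile("s1", "monkey", dose = 1000, time = t,
                         conc = 100 * exp(-0.6931 * t))
  r <- run_nca(p)
  expect_equal(r$auc_inf, 100 / 0.6931, tolerance = 0.01)       # C0/k
  expect_equal(r$cl, 1000 * 0.6931 / 100, tolerance = 0.01)     # D k / C0
  expect_equal(r$mrt, 1 / 0.6931, tolerance = 0.01)             # 1/k
  expect_equal(r$vss, 1000 / 100, tolerance = 0.01)             # D / C0
  expect_equal(r$t_half, 1, tolerance = 0.01)
})

test_that("AUClast is returned even when the terminal slope is not", {
  p <- conc_time_profile("s1", "rat", dose = 10, time = c(0, 1),
                         conc = c(10, 10))
  r <- run_nca(p)
  expect_equal(r$auc_last, 10)
  expect_true(is.na(r$auc_inf) && is.na(r$cl) && is.na(r$t_half))
})

test_that("NCA identities hold exactly for every result", {
  set.seed(99)
  t <- monkey_schedule()
  for (i in 1:10) {
    conc <- (50 + 100 * runif(1)) * exp(-runif(1, 0.3, 1.5) * t) *
      exp(rnorm(length(t), 0, 0.1))
    r <- run_nca(conc_time_profile("s", "monkey", 1000, time = t,
                                   conc = conc))
    expect_equal(r$t_half, log(2) / r$lambda_z)
    expect_equal(r$cl, r$dose / r$auc_inf)
    expect_equal(r$vss, r$cl * r$mrt)
  }
})

test_that("AUClast is invariant to a collinear midpoint", {
  p1 <- conc_time_profile("s", "rat", 10, time = c(0, 1, 2),
                          conc = c(0, 10, 5))
  p2 <- conc_time_profile("s", "rat", 10, time = c(0, 0.5, 1, 2),
                          conc = c(0, 5, 10, 5))
  expect_equal(run_nca(p1)$auc_last, run_nca(p2)$auc_last)
})

test_that("NCA recovers the clearance of a noise-free simulation", {
  phys <- load_physiology("monkey")
  cl_true <- 0.1 * phys$body_weight               # 100 ml/kg/h as L/h
  mod <- build_model(phys, default_kps(), cl_true)
  sim <- simulate_pbpk(mod, 6, dosing = list(dose_event(11.5 * 6)))
  t <- monkey_schedule()
  conc <- approx(sim$time, sim$conc_plasma, t)$y
  r <- run_nca(conc_time_profile("m1", "monkey", 11500, time = t,
                                 conc = conc))
  expect_equal(r$cl, 100, tolerance = 0.02)
})

test_that("BLQ rules: pre-dose zeroed, embedded dropped, trailing trimmed", {
  t <- c(0, 0.5, 1, 2, 4, 6)
  conc <- c(NA, 10, NA, 4, NA, NA)
  blq <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  p <- conc_time_profile("s", "monkey", 100, time = t, conc = conc,
                         blq = blq)
  cleaned <- oligopbpk:::.clean_profile(p)
  expect_equal(cleaned$time, c(0, 0.5, 2))
  expect_equal(cleaned$conc, c(0, 10, 4))
})

test_that("profile construction rejects malformed series", {
  expect_error(conc_time_profile("s", "rat", 1, time = c(1, 1),
                                 conc = c(1, 2)), "increasing")
  expect_error(conc_time_profile("s", "rat", 1, time = c(1, 2),
                                 conc = c(-1, 2)), ">= 0")
  expect_error(conc_time_profile("s", "rat", 1, time = 1,
                                 conc = c(1, 2)), "equal length")
})

test_that("nca_table and its summary aggregate by dose group", {
  design <- monkey_iv_design()
  truth <- list(physiology = load_physiology("monkey"),
                kps = default_kps(), cl_ml_kg_h = 100)
  data <- generate_plasma_study(design, truth,
                                variability_model(0, 0, 0), seed = 1)
  tab <- nca_table(data)
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$dose_mg_kg), c(11.5, 23, 46))
  s <- summarize_nca(tab)
  expect_true(all(c("dose_11.5_mg_kg", "dose_46_mg_kg") %in% names(s)))
  expect_equal(nrow(s), 6)
})
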