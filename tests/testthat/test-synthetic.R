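monkey_truth <- function() {
  list(physiology = load_physiology("monkey"), kps = default_kps(),
       cl_ml_kg_h = 100, blood_plasma_ratio = 1)
}

test_that("zero variability reproduces the truth simulation exactly", {
  design <- monkey_iv_design()
  truth <- monkey_truth()
  data <- generate_plasma_study(design, truth, variability_model(0, 0, 0),
                                seed = 5)
  phys <- truth$physiology
  mod <- build_model(phys, truth$kps, truth$cl_ml_kg_h / 1000 *
                       phys$body_weight)
  for (dose in design$doses_mg_kg) {
    sim <- simulate_pbpk(mod, 6,
                         dosing = list(dose_event(dose * phys$body_weight)))
    expected <- approx(sim$time, sim$conc_plasma, design$times_h)$y
    subj <- unique(data$subject[data$dose_mg_kg == dose &
                                  data$matrix == "plasma"])
    for (s in subj) {
      obs <- data$conc_ug_ml[data$subject == s & data$matrix == "plasma"]
      expect_equal(obs, expected)
    }
  }
})

test_that("generation is deterministic in the seed and leaves RNG state", {
  design <- monkey_iv_design()
  truth <- monkey_truth()
  set.seed(1); before <- runif(1)
  d1 <- generate_plasma_study(design, truth, seed = 123)
  d2 <- generate_plasma_study(design, truth, seed = 123)
  expect_identical(d1, d2)
  d3 <- generate_plasma_study(design, truth, seed = 124)
  expect_false(identical(d1$conc_ug_ml, d3$conc_ug_ml))
  b1 <- generate_binding_study(seed = 9)
  b2 <- generate_binding_study(seed = 9)
  expect_identical(b1, b2)
})

test_that("generated studies respect LLOQ, non-negativity and BLQ excreta", {
  data <- generate_plasma_study(monkey_iv_design(), monkey_truth(),
                                seed = 20211103)
  expect_true(all(data$conc_ug_ml >= 0, na.rm = TRUE))
  expect_true(all(data$conc_ug_ml[!data$blq] >= 0.18, na.rm = TRUE))
  expect_true(all(is.na(data$conc_ug_ml[data$blq])))
  excreta <- data[data$matrix %in% c("urine", "feces"), ]
  expect_gt(nrow(excreta), 0)
  expect_true(all(excreta$blq))
})

test_that("an end-to-end run on proportional truth estimates slope near 1", {
  data <- generate_plasma_study(monkey_iv_design(), monkey_truth(),
                                variability_model(0.15, 0.15, 0.10),
                                seed = 20211103)
  tab <- nca_table(data)
  fit <- fit_power_model(data.frame(dose = tab$dose_mg_kg,
                                    value = tab$auc_inf),
                         parameter = "auc_inf")
  expect_gt(fit$slope, 0.8)
  expect_lt(fit$slope, 1.2)
})

test_that("noise-free generated profiles return the truth clearance", {
  data <- generate_plasma_study(monkey_iv_design(), monkey_truth(),
                                variability_model(0, 0, 0), seed = 2)
  tab <- nca_table(data)
  expect_true(all(abs(tab$cl - 100) / 100 < 0.02))
})

test_that("ordered truth Kps reproduce the observed tissue AUC ranking", {
  kps <- rat_tissue_truth_kps()
  expect_true(all(kps[c("kidney", "spleen", "liver", "fat", "jejunum",
                        "stomach", "lung", "heart", "muscle")] ==
                    sort(kps, decreasing = TRUE)))
  data <- generate_tissue_study(kps = kps, seed = 20211103)
  rank <- tissue_auc_ranking(data)
  expect_equal(rank$matrix,
               c("plasma", "muscle", "heart", "lung", "stomach", "jejunum",
                 "fat", "liver", "spleen", "kidney"))
})

test_that("unit Kps equilibrate all tissues with plasma at late times", {
  kps1 <- setNames(rep(1, 9), setdiff(rat_tissue_design()$matrices,
                                      "plasma"))
  data <- generate_tissue_study(kps = kps1, noise_cv = 0)
  late <- data[data$time_h == 6, ]
  plasma <- late$conc_ug_ml[late$matrix == "plasma"]
  expect_true(all(abs(late$conc_ug_ml / plasma - 1) < 0.02))
})

test_that("tissue outputs are linear in dose with invariant ID%/g", {
  d1 <- generate_tissue_study(dose_mg_kg = 25, noise_cv = 0)
  d2 <- generate_tissue_study(dose_mg_kg = 50, noise_cv = 0)
  expect_equal(d2$conc_ug_ml, 2 * d1$conc_ug_ml, tolerance = 1e-6)
  expect_equal(d2$id_pct_per_g, d1$id_pct_per_g, tolerance = 1e-6)
  # homogenate dilution factor 11 is applied and inverted
  expect_equal(d1$conc_ug_ml, 11 * d1$homogenate_conc_ug_ml)
  expect_error(generate_tissue_study(kps = c(heart = 2)), "missing truth Kp")
})

test_that("binding generation recovers the true fraction unbound", {
  exact <- generate_binding_study(fu_truth = c(human_plasma = 0.01),
                                  noise_cv = 0, seed = 1)
  fu <- fraction_unbound(exact$c_buffer, exact$c_plasma)
  expect_equal(fu$fu_percent, rep(1, nrow(exact)))

  t3 <- binding_table(generate_binding_study(
    fu_truth = c(human_plasma = 0.04), noise_cv = 0, seed = 1))
  expect_equal(t3$bound_mean, rep(96, 3))

  noisy <- generate_binding_study(fu_truth = c(monkey_plasma = 0.03),
                                  noise_cv = 0.05, n_rep = 10, seed = 4)
  est <- mean(fraction_unbound(noisy$c_buffer, noisy$c_plasma)$fu_percent)
  expect_lt(abs(est - 3), 3 * 0.05 * 3)   # within 3 noise SDs of truth
  expect_error(generate_binding_study(fu_truth = c(a = 1.5)), "fu_truth")
})

test_that("study design invariants are enforced", {
  expect_error(study_design("rat", -1, 3, 1:3), "doses")
  expect_error(study_design("rat", 1, 3, c(1, 1)), "increasing")
  expect_error(study_design("rat", 1, 0, 1:3), "subject")
})
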