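toy_tissue <- list(tissue = "toy", f_ew = 0.3, f_iw = 0.7, f_nl = 0,
                   f_np = 0, ap_mg_g = 0, protein_ratio = 0, ph_iw = 7.4)

test_that("physchem profile enforces its invariants", {
  expect_error(physchem_profile(0, "neutral"), "molecular_weight")
  expect_error(physchem_profile(100, "neutral", fup = 0), "fup")
  expect_error(physchem_profile(100, "neutral", fup = 1.2), "fup")
  expect_error(physchem_profile(100, "monoprotic_acid"), "pKa")
  expect_error(physchem_profile(100, "zwitterion", pka = 4), "pKa")
  expect_s3_class(physchem_profile(6044.4, "polyanion"), "physchem_profile")
})

test_that("Kp reduces to unity for a fully aqueous tissue and free drug", {
  drug <- physchem_profile(300, "neutral", logp = 0.5, fup = 1)
  expect_equal(kp_rodgers_single(drug, toy_tissue), 1)
})

test_that("Kp matches a hand evaluation of the equation on toy inputs", {
  drug <- physchem_profile(300, "neutral", logp = 1, fup = 0.5)
  muscle <- load_tissue_composition()
  muscle <- muscle[muscle$tissue == "muscle", ]
  # independent hand evaluation: neutral species, no ionization terms
  p <- 10
  lipid_t <- p * 0.0238 + (0.3 * p + 0.7) * 0.0072
  lipid_p <- p * 0.0023 + (0.3 * p + 0.7) * 0.0013
  prot <- 0.064 * (1 / 0.5 - 1 - lipid_p)
  expected <- 0.5 * (0.118 + 0.630 + lipid_t + prot)
  expect_equal(kp_rodgers_single(drug, muscle), expected, tolerance = 1e-12)
})

test_that("stronger plasma binding raises the binding-corrected Kp", {
  comp <- load_tissue_composition()
  liver <- comp[comp$tissue == "liver", ]
  lo <- physchem_profile(300, "neutral", logp = 0, fup = 0.01)
  hi <- physchem_profile(300, "neutral", logp = 0, fup = 1)
  expect_gt(kp_rodgers_single(lo, liver, reference = "unbound_plasma"),
            kp_rodgers_single(hi, liver, reference = "unbound_plasma"))
  # and the two references differ exactly by fup
  expect_equal(kp_rodgers_single(lo, liver),
               0.01 * kp_rodgers_single(lo, liver,
                                        reference = "unbound_plasma"))
})

test_that("Lukacova dispatch agrees with the direct equation branches", {
  comp <- load_tissue_composition()
  kidney <- comp[comp$tissue == "kidney", ]
  neutral <- physchem_profile(300, "neutral", logp = 1.5, fup = 0.3)
  expect_identical(kp_lukacova(neutral, kidney),
                   kp_rodgers_single(neutral, kidney))
  # a polyanion behaves as the fully ionized limit of the acid branch
  poly <- physchem_profile(6044.4, "polyanion", logp = -2, fup = 0.02)
  acid_limit <- physchem_profile(6044.4, "monoprotic_acid", pka = -2,
                                 logp = -2, fup = 0.02)
  expect_equal(kp_lukacova(poly, kidney),
               kp_rodgers_single(acid_limit, kidney), tolerance = 1e-4)
  # a strong base takes the electrostatic branch and differs
  base <- physchem_profile(300, "monoprotic_base", pka = 9, logp = 1,
                           fup = 0.3, blood_plasma_ratio = 1.2)
  expect_false(isTRUE(all.equal(kp_lukacova(base, kidney),
                                kp_rodgers_single(base, kidney))))
})

test_that("hydrophilic unbound drug cannot concentrate in lean tissue", {
  comp <- load_tissue_composition()
  muscle <- comp[comp$tissue == "muscle", ]
  drug <- physchem_profile(300, "neutral", logp = -3, fup = 1)
  expect_lte(kp_lukacova(drug, muscle), 1)
})

test_that("Kp is non-negative and monotone non-decreasing in logP", {
  comp <- load_tissue_composition()
  grid <- seq(-4, 4, by = 0.25)
  for (tn in c("adipose", "muscle", "liver", "brain")) {
    tis <- comp[comp$tissue == tn, ]
    for (cls in c("neutral", "monoprotic_acid", "polyanion")) {
      drug0 <- function(lp) physchem_profile(
        300, cls, pka = if (cls == "monoprotic_acid") 4.5 else numeric(),
        logp = lp, fup = 0.1)
      kp <- vapply(grid, function(lp) kp_lukacova(drug0(lp), tis),
                   numeric(1))
      expect_true(all(kp >= 0))
      expect_true(all(diff(kp) >= -1e-12))
    }
  }
  # randomized non-negativity across classes and tissues
  set.seed(42)
  for (i in 1:50) {
    cls <- sample(c("neutral", "monoprotic_acid", "monoprotic_base",
                    "zwitterion", "polyanion"), 1)
    pka <- switch(cls, monoprotic_acid = runif(1, 2, 10),
                  monoprotic_base = runif(1, 2, 11),
                  zwitterion = sort(runif(2, 2, 10)), numeric())
    drug <- physchem_profile(500, cls, pka = pka,
                             logp = runif(1, -4, 5),
                             fup = runif(1, 0.005, 1),
                             blood_plasma_ratio = runif(1, 0.6, 1.5))
    tis <- comp[sample(nrow(comp), 1), ]
    expect_gte(kp_lukacova(drug, tis), 0)
  }
})

test_that("Vss assembles linearly from Kps and tissue volumes", {
  phys <- toy_physiology(3, c(big = 10, small = 5))
  expect_equal(vss_from_kps(c(big = 2, small = 0.5), phys), 25.5)
  expect_equal(vss_from_kps(c(big = 0, small = 0), phys), 3)
  expect_equal(vss_from_kps(c(big = 1, small = 1), phys), 3 + 15)
  # linear in each Kp
  base <- vss_from_kps(c(big = 1, small = 1), phys)
  bumped <- vss_from_kps(c(big = 1.5, small = 1), phys)
  expect_equal(bumped - base, 0.5 * 10)
  expect_error(vss_from_kps(c(big = 1), phys), "small")
})
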