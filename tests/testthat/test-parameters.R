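test_that("bundled physiologies load with the tabulated values", {
  rat <- load_species_physiology("rat")
  kidney <- subset(rat$tissues, name == "kidney")
  expect_equal(kidney$volume_ml, 4.588)
  expect_equal(kidney$flow_ml_s, 0.18019)

  human <- load_species_physiology("human")
  expect_equal(human$venous_volume_ml, 4296.34)
  expect_equal(human$cardiac_output_ml_s, 98.1779)

  expect_error(load_species_physiology("dog"), "unknown species")
})

test_that("tissue blood flows reconcile with cardiac output", {
  for (sp in c("mouse", "rat", "human")) {
    phys <- load_species_physiology(sp)
    draining <- setdiff(cefapbpk:::PBPK_TISSUES, c("lung", "spleen"))
    qsum <- sum(phys$tissues$flow_ml_s[phys$tissues$name %in% draining])
    expect_lt(abs(qsum - phys$cardiac_output_ml_s) /
                phys$cardiac_output_ml_s, 0.02)
  }
})

test_that("overrides apply and invalid overrides or values error", {
  phys <- load_species_physiology("rat",
                                  overrides = list("tissue.kidney.kp" = 3))
  expect_equal(phys$tissues$kp[phys$tissues$name == "kidney"], 3)
  expect_error(
    load_species_physiology("rat", overrides = list("tissue.gizzard.kp" = 1)),
    "no configuration key")
  expect_error(
    load_species_physiology("rat",
                            overrides = list("tissue.kidney.volume_ml" = -1)),
    "must be > 0")
})

test_that("physiologies round-trip through serialization", {
  for (sp in c("mouse", "human")) {
    phys <- load_species_physiology(sp)
    path <- withr::local_tempfile(fileext = ".conf")
    write_species_physiology(phys, path)
    again <- load_species_physiology(sp, path = path)
    expect_equal(again, phys)
  }
})

test_that("body weight follows from dose arithmetic", {
  expect_equal(derive_body_weight(375.5, 5), 75.1)
  expect_equal(derive_body_weight(0.62, 2), 0.31)
  # 528 nmol/g * 363.39 g/mol = 191.87 ug/g; total mouse dose 4.79 mg
  expect_equal(derive_body_weight(4.79, 528 * 363.39 / 1000), 0.025,
               tolerance = 2e-3)
  expect_error(derive_body_weight(-1, 5), "positive")
  expect_error(derive_body_weight(1, 0), "positive")
})

test_that("structural Vss is the Kp-weighted volume plus plasma", {
  mouse <- load_species_physiology("mouse")
  # blood-only limit: with all Kp -> 0 only the plasma volume remains
  tiny <- mouse
  tiny$tissues$kp <- rep(1e-12, nrow(tiny$tissues))
  expect_equal(compute_pbpk_vss(tiny),
               (1 - mouse$haematocrit) *
                 (mouse$arterial_volume_ml + mouse$venous_volume_ml) / 1000,
               tolerance = 1e-6)
  # linearity: doubling one Kp adds exactly Kp_t * V_t
  bumped <- mouse
  i <- which(bumped$tissues$name == "muscle")
  bumped$tissues$kp[i] <- 2 * bumped$tissues$kp[i]
  expect_equal(compute_pbpk_vss(bumped) - compute_pbpk_vss(mouse),
               mouse$tissues$kp[i] * mouse$tissues$volume_ml[i] / 1000)
})

test_that("drug properties load and validate", {
  drug <- load_drug_properties("human")
  expect_equal(drug$molecular_weight_g_mol, 363.39)
  expect_equal(drug$fup, 0.719)
  expect_equal(drug$renal_clearance_l_h, 8.50)
  expect_equal(load_drug_properties("mouse")$renal_clearance_l_h, 0.031)
  expect_error(load_drug_properties("human", overrides = list(fup = 1.5)),
               "fup")
})

test_that("dose events validate their fields", {
  d <- dose_event("oral", 1126.5)
  expect_equal(d$amount_mg, 1126.5)
  expect_error(dose_event("iv_bolus", -1), "non-negative")
  expect_error(dose_event("iv_bolus", 1, time_h = -2), "non-negative")
  expect_error(dose_event("intramuscular", 1))
})
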