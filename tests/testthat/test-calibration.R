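test_that("clearance is recovered from noiseless profiles in all species", {
  for (sp in c("mouse", "rat")) {
    model <- species_model(sp)
    dose <- dose_event("iv_bolus", if (sp == "mouse") 4.79 else 0.62)
    obs <- generate_observed_profile(model, dose, noise = noise_model(cv = 0))
    fit <- fit_clearance(obs, model, dose, bounds = c(1e-3, 10))
    expect_equal(fit$cl_l_h, model$cl_renal, tolerance = 0.01)
    expect_false(fit$boundary_flag)
  }
  human <- human_model()
  dose <- dose_event("oral", 1126.5)
  obs <- generate_observed_profile(human, dose, gut = human_gut(),
                                   noise = noise_model(cv = 0))
  fit <- fit_clearance(obs, human, dose, gut = human_gut(),
                       bounds = c(0.5, 50))
  expect_equal(fit$cl_l_h, human$cl_renal, tolerance = 0.01)
})

test_that("a fit whose bounds exclude the truth is flagged at the boundary", {
  model <- rat_model()
  dose <- dose_event("iv_bolus", 0.62)
  obs <- generate_observed_profile(model, dose, noise = noise_model(cv = 0))
  expect_warning(fit <- fit_clearance(obs, model, dose,
                                      bounds = c(0.3, 0.6)),
                 "bound")
  expect_true(fit$boundary_flag)
})

test_that("clearance recovery from noisy data is accurate for a pinned seed", {
  model <- rat_model()
  dose <- dose_event("iv_bolus", 0.62)
  obs <- generate_observed_profile(model, dose,
                                   sample_times_h = c(5, 15, 30, 60, 90,
                                                      120, 150, 180, 240) / 60,
                                   noise = noise_model(cv = 0.1, seed = 42))
  fit <- fit_clearance(obs, model, dose, bounds = c(0.01, 2))
  expect_equal(fit$cl_l_h, 0.18, tolerance = 0.1)
})

test_that("allometric regression reproduces exact power laws and printed constants", {
  exact <- allometric_fit(2 * c(0.02, 1, 30)^0.75, c(0.02, 1, 30))
  expect_equal(exact$a, 2)
  expect_equal(exact$b, 0.75)
  expect_equal(exact$r_squared, 1)

  bw <- c(derive_body_weight(4.79, 528 * 363.39 / 1000),
          derive_body_weight(0.62, 2),
          derive_body_weight(375.5, 5))
  vss_fit <- allometric_fit(c(0.012, 0.159, 24.747), bw)
  expect_equal(vss_fit$a, 0.4288, tolerance = 5e-3)
  expect_equal(vss_fit$b, 0.9476, tolerance = 5e-3)
  cl_fit <- allometric_fit(c(0.031, 0.18, 8.50), bw)
  expect_equal(cl_fit$a, 0.4108, tolerance = 5e-3)
  expect_equal(cl_fit$b, 0.7012, tolerance = 5e-3)

  # scale equivariance: a scales with y, b and R^2 do not move
  scaled <- allometric_fit(5 * c(0.012, 0.159, 24.747), bw)
  expect_equal(scaled$a, 5 * vss_fit$a)
  expect_equal(scaled$b, vss_fit$b)
  expect_equal(scaled$r_squared, vss_fit$r_squared)
  expect_error(allometric_fit(c(1, 2), c(1, 2)), "3 species")
  expect_error(allometric_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("PSA: clearance scales IV AUC inversely, Kp leaves it unchanged", {
  model <- rat_model()
  dose <- dose_event("iv_bolus", 0.62)
  cl_sweep <- psa_sweep(model, dose, "cl_renal", factors = c(0.5, 1, 2))
  base_auc <- cl_sweep$auc_0_inf[cl_sweep$factor == 1]
  expect_equal(cl_sweep$auc_0_inf, base_auc / cl_sweep$factor,
               tolerance = 1e-3)

  kp_sweep <- psa_sweep(model, dose, "kp_muscle", factors = c(0.1, 1, 10))
  expect_lt(diff(range(kp_sweep$auc_0_inf)) / base_auc, 0.01)
  expect_error(psa_sweep(model, dose, "kp_gizzard"), "unknown")

  # for oral dosing, muscle Kp moves the plasma Cmax but not the AUC
  oral_kp <- psa_sweep(human_model(), dose_event("oral", 1126.5),
                       "kp_muscle", gut = human_gut(),
                       factors = c(0.1, 10))
  expect_gt(oral_kp$cmax[1], oral_kp$cmax[2])
  expect_lt(abs(diff(oral_kp$auc_0_inf)) / oral_kp$auc_0_inf[1], 0.01)
})

test_that("PSA: oral exposure is insensitive to solubility and passive Peff", {
  human <- human_model()
  dose <- dose_event("oral", 1126.5)
  sol <- psa_sweep(human, dose, "solubility", gut = human_gut(),
                   factors = c(0.1, 1, 10))
  expect_lt(diff(range(sol$auc_0_inf)) / sol$auc_0_inf[2], 0.01)
  peff <- psa_sweep(human, dose, "peff", gut = human_gut(),
                    factors = c(0.1, 1, 10))
  expect_lt(diff(range(peff$auc_0_inf)) / peff$auc_0_inf[2], 0.05)
  # but capacity of the carrier matters
  vmax <- psa_sweep(human, dose, "vmax_scale", gut = human_gut(),
                    factors = c(0.1, 1))
  expect_lt(vmax$auc_0_inf[1], 0.8 * vmax$auc_0_inf[2])
})

test_that("slowing the release rate degrades exposure monotonically", {
  rr <- compare_release_rates(human_model(), t85_grid_h = c(0.5, 2, 6))
  expect_equal(rr$cmax_err_pct[1], 0)
  expect_equal(rr$auc_err_pct[1], 0)
  expect_gt(rr$cmax_err_pct[3], rr$cmax_err_pct[2])
  expect_gt(rr$auc_err_pct[3], rr$auc_err_pct[2])
  expect_error(compare_release_rates(human_model(), t85_grid_h = c(1, 2)),
               "reference")
})
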