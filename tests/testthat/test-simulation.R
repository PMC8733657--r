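test_that("NCA recovers the closed form of a mono-exponential profile", {
  t <- seq(0, 40, by = 0.01)
  prof <- data.frame(time = t, conc = 10 * exp(-0.5 * t))
  m <- pk_metrics(prof, dose_mg = 100, route = "iv_bolus")
  expect_equal(m$cmax, 10)
  expect_equal(m$auc_0_inf, 20, tolerance = 1e-4)
  expect_equal(m$lambda_z, 0.5, tolerance = 1e-4)
  expect_equal(m$cl_l_h, 5, tolerance = 1e-4)
  expect_equal(m$mrt_h, 2, tolerance = 1e-3)
  expect_equal(m$vss_l, 10, tolerance = 1e-3)
})

test_that("trapezoid AUC and the extrapolation refusal behave on short profiles", {
  m <- pk_metrics(data.frame(time = c(0, 1), conc = c(10, 0)),
                  dose_mg = 1, route = "iv_bolus")
  expect_equal(m$auc_0_t, 5)
  expect_true(m$lambda_z_flag)
  expect_true(is.na(m$auc_0_inf))

  rising <- data.frame(time = 0:5, conc = c(1, 2, 4, 8, 16, 32))
  mr <- pk_metrics(rising, dose_mg = 1, route = "iv_bolus")
  expect_true(mr$lambda_z_flag)
  expect_error(pk_metrics(data.frame(time = 0, conc = 1), dose_mg = 1,
                          route = "iv_bolus"), "non-empty")
})

test_that("NCA Vss agrees with the structural Vss on IV runs", {
  for (sp in c("mouse", "rat")) {
    model <- species_model(sp)
    m <- pk_metrics(simulate_pk(model, dose_event("iv_bolus", 1)))
    expect_equal(m$vss_l, compute_pbpk_vss(model$phys), tolerance = 0.1)
    expect_equal(m$cl_l_h, model$cl_renal, tolerance = 0.02)
  }
})

test_that("results are converged with respect to solver tolerances", {
  base <- pk_metrics(simulate_pk(rat_model(), dose_event("iv_bolus", 0.62)))
  tight <- pk_metrics(simulate_pk(rat_model(), dose_event("iv_bolus", 0.62),
                                  rtol = 5e-9, atol = 5e-11))
  expect_equal(tight$auc_0_inf, base$auc_0_inf, tolerance = 1e-3)
  expect_equal(tight$cmax, base$cmax, tolerance = 1e-3)
})

test_that("oral dosing with near-complete absorption obeys AUC = Fa * Dose / CL", {
  human <- human_model()
  sim <- simulate_pk(human, dose_event("oral", 1126.5), gut = human_gut())
  fa <- compute_fa(sim)
  m <- pk_metrics(sim)
  expect_equal(m$auc_0_inf, fa * 1126.5 / human$cl_renal, tolerance = 0.02)
})

test_that("tissue exposure ordering follows Kp for well-perfused organs", {
  sim <- simulate_pk(human_model(), dose_event("oral", 1126.5),
                     gut = human_gut())
  cmax <- vapply(cefapbpk:::PBPK_TISSUES, function(tn)
    max(sim$conc[[tn]]), numeric(1))
  expect_equal(names(which.max(cmax)), "kidney")
  expect_gt(cmax[["kidney"]], max(sim$plasma))
  expect_gt(cmax[["liver"]], cmax[["brain"]])
})

test_that("zero dose and input validation", {
  expect_error(simulate_pk(rat_model(), dose_event("iv_bolus", 1),
                           t_end_h = -1), "t_end_h")
  expect_error(simulate_pk(rat_model(), dose_event("iv_bolus", 1),
                           times = c(0, 0, 1)), "strictly increasing")
  expect_error(simulate_pk(human_model(), dose_event("oral", 1)),
               "gut model")
})

test_that("profile CSV export is tidy and numerically faithful", {
  sim <- simulate_pk(rat_model(), dose_event("iv_bolus", 0.62),
                     times = seq(0, 4, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(sim, path, compartments = c("venous", "kidney"))
  d <- utils::read.csv(path)
  expect_equal(names(d), c("time_h", "compartment", "conc_ug_per_ml"))
  expect_equal(d$conc_ug_per_ml[d$compartment == "kidney"],
               sim$conc$kidney, tolerance = 1e-12)
})
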