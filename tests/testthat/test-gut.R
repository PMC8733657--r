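test_that("gut segments load with the segmental PEPT1 expression", {
  seg <- load_gut_segments()
  expect_equal(seg$name[1], "stomach")
  expect_equal(seg$pept1_mg[seg$name == "duodenum"], 16.28)
  expect_equal(seg$pept1_mg[seg$name == "jejunum1"], 87.84)
  expect_equal(sum(seg$pept1_mg[seg$name %in% c("stomach", "caecum",
                                                "colon")]), 0)
  expect_equal(attr(seg, "km_mg_l"), 860.31)
})

test_that("carrier flux is Michaelis-Menten in the luminal concentration", {
  seg <- load_gut_segments()
  duo <- seg[seg$name == "duodenum", ]
  kin <- transporter_kinetics(scale = 1)
  vmax <- kin$vmax_ug_s_mg * duo$pept1_mg * 3.6  # mg/h plateau
  expect_equal(transporter_flux(860.31, duo, kin), vmax / 2)
  expect_equal(transporter_flux(0, duo, kin), 0)
  expect_equal(transporter_flux(1e12, duo, kin), vmax, tolerance = 1e-6)
  # doubling the capacity multiplier doubles the flux
  kin2 <- transporter_kinetics(scale = 2)
  expect_equal(transporter_flux(100, duo, kin2),
               2 * transporter_flux(100, duo, kin))
  expect_error(transporter_flux(-1, duo, kin), "negative")
})

test_that("passive uptake scales as 2 Peff / r", {
  seg <- load_gut_segments()
  duo <- seg[seg$name == "duodenum", ]
  peff <- 3e-6
  # ka = 2 * Peff / r in 1/s, converted to 1/h
  expect_equal(passive_absorption_rate(1, duo, peff),
               2 * peff / 1.6 * 3600)
  expect_equal(passive_absorption_rate(1, duo, 0), 0)
  wider <- duo
  wider$radius_cm <- 2 * duo$radius_cm
  expect_equal(passive_absorption_rate(1, wider, peff),
               passive_absorption_rate(1, duo, peff) / 2)
})

test_that("first-order dissolution honours T85% and the solubility gate", {
  spec <- dissolution_spec("first_order", t85_h = 2)
  kd <- log(1 / 0.15) / 2
  expect_equal(kd, 0.9486, tolerance = 1e-4)
  expect_equal(dissolution_transfer(10, 0, spec, 12.44), kd * 10)
  expect_equal(dissolution_transfer(0, 0, spec, 12.44), 0)
  expect_equal(dissolution_transfer(10, 12440, spec, 12.44), 0)
  expect_error(dissolution_spec("first_order"), "t85")
})

test_that("oral simulations conserve mass and the no-absorption limit is total faecal loss", {
  human <- human_model()
  sim <- simulate_pk(human, dose_event("oral", 1126.5), gut = human_gut())
  expect_lt(mass_balance_check(sim), 1e-3)

  # no transporter, no passive permeation: everything leaves in faeces
  human0 <- human
  human0$drug$passive_peff_cm_s <- 0
  g0 <- gut_model(pept1_enabled = FALSE)
  s0 <- simulate_pk(human0, dose_event("oral", 100), gut = g0, t_end_h = 200)
  expect_equal(utils::tail(s0$gut$absorbed, 1), 0)
  expect_equal(compute_fa(s0), 0)
  expect_equal(utils::tail(s0$gut$faeces, 1), 100, tolerance = 1e-3)
  expect_lt(mass_balance_check(s0), 1e-3)
})

test_that("fraction absorbed reproduces the transporter knockout contrast", {
  human <- human_model()
  with_t <- simulate_pk(human, dose_event("oral", 1126.5), gut = human_gut())
  expect_equal(compute_fa(with_t), 0.999, tolerance = 0.005)
  without <- simulate_pk(human, dose_event("oral", 1126.5),
                         gut = gut_model(pept1_enabled = FALSE))
  expect_lt(abs(compute_fa(without) - 0.078), 0.04)
  expect_error(compute_fa(simulate_pk(rat_model(),
                                      dose_event("iv_bolus", 0.62))),
               "oral")
})

test_that("fraction absorbed is monotone in capacity, permeability and transit", {
  human <- human_model()
  fa_scale <- function(s) {
    g <- human_gut()
    g$kinetics$scale <- s
    compute_fa(simulate_pk(human, dose_event("oral", 1126.5), gut = g,
                           n_points = 101))
  }
  fas <- vapply(c(0, 20, 80, 320), fa_scale, numeric(1))
  expect_true(all(diff(fas) > 0))

  fa_peff <- function(p) {
    h <- human
    h$drug$passive_peff_cm_s <- p
    compute_fa(simulate_pk(h, dose_event("oral", 1126.5),
                           gut = gut_model(pept1_enabled = FALSE),
                           n_points = 101))
  }
  expect_true(all(diff(vapply(c(0, 3e-6, 3e-5), fa_peff, numeric(1))) > 0))

  # slower transit leaves more time for uptake
  seg_slow <- load_gut_segments()
  seg_slow$transit_h <- seg_slow$transit_h * 2
  fa_slow <- compute_fa(simulate_pk(human, dose_event("oral", 1126.5),
                                    gut = gut_model(segments = seg_slow,
                                                    pept1_enabled = FALSE),
                                    n_points = 101))
  expect_gt(fa_slow, fa_peff(3e-6))
})

test_that("dose saturation: luminal concentrations far below Km make Fa dose-independent", {
  human <- human_model()
  g <- human_gut()
  fa_small <- compute_fa(simulate_pk(human, dose_event("oral", 0.1),
                                     gut = g, n_points = 101))
  fa_small2 <- compute_fa(simulate_pk(human, dose_event("oral", 0.2),
                                      gut = g, n_points = 101))
  expect_equal(fa_small, fa_small2, tolerance = 1e-3)
})

test_that("transporter calibration is a fixed point and precipitation is inert", {
  human <- human_model()
  scale <- calibrate_transporter_scale(0.99, human, dose_mg = 1126.5,
                                       bracket = c(0, 64))
  g <- human_gut()
  g$kinetics$scale <- as.numeric(scale)
  fa <- compute_fa(simulate_pk(human, dose_event("oral", 1126.5), gut = g))
  expect_equal(fa, 0.99, tolerance = 0.005)
  expect_error(calibrate_transporter_scale(0.01, human),
               "passive absorption alone")

  # precipitation re-transfer never triggers at cefadroxil's solubility
  g1 <- gut_model(dissolution = dissolution_spec("first_order", t85_h = 1))
  g2 <- g1
  g2$precipitation <- FALSE
  s1 <- simulate_pk(human, dose_event("oral", 1126.5), gut = g1,
                    n_points = 101)
  s2 <- simulate_pk(human, dose_event("oral", 1126.5), gut = g2,
                    n_points = 101)
  expect_equal(s1$plasma, s2$plasma, tolerance = 1e-8)
})
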