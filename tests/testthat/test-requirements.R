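test_that("maintenance ME scales with metabolic body weight", {
  expect_equal(me_maintenance(415), 0.631 * 415^0.75, tolerance = 1e-12)
  expect_equal(me_maintenance(415), 58.0, tolerance = 1e-3)
  expect_equal(me_maintenance(50, is_calf = TRUE), 0.53 * 50^0.75,
               tolerance = 1e-12)
  expect_equal(me_maintenance(50, is_calf = TRUE), 9.97, tolerance = 1e-2)
  expect_equal(me_maintenance(1), 0.631)
  ## strictly increasing in body weight
  expect_true(all(diff(me_maintenance(seq(50, 700, by = 5))) > 0))
})

test_that("ME cost of milk follows the fat-dependent linear form", {
  expect_equal(me_per_kg_milk(46.3, 0.6), (0.041 * 46.3 + 1.51) / 0.6,
               tolerance = 1e-12)
  expect_equal(me_per_kg_milk(46.3, 0.6), 5.680, tolerance = 1e-3)
  expect_equal(me_per_kg_milk(46.6, 0.6), 5.700, tolerance = 1e-3)
  expect_equal(me_per_kg_milk(0.001, 1), 1.51, tolerance = 1e-4)
  expect_error(me_per_kg_milk(46, 0), class = "dairysim_domain_error")

  ## lactation ME is linear in yield
  expect_equal(me_lactation(0, 46.3, 0.6), 0)
  expect_equal(me_lactation(20, 46.3, 0.6), 113.6, tolerance = 1e-1)
  expect_equal(me_lactation(1, 0.001, 1), 1.51, tolerance = 1e-4)
  y <- seq(0, 30, by = 0.5)
  expect_equal(me_lactation(y, 46.3, 0.6), y * me_per_kg_milk(46.3, 0.6))
})

test_that("activity ME covers horizontal and vertical locomotion at 0.7 efficiency", {
  expect_equal(me_activity(400, 0, 0), 0)
  expect_equal(me_activity(400, 1000, 0), 2.6 * 400 * 1000 / 1e6 / 0.7,
               tolerance = 1e-12)
  expect_equal(me_activity(400, 1000, 0), 1.486, tolerance = 1e-3)
  expect_equal(me_activity(400, 0, 100), 1.6, tolerance = 1e-9)
  expect_error(me_activity(400, -1, 0), class = "dairysim_domain_error")
})

test_that("gestation ME applies only in the last eight weeks", {
  expect_equal(me_gestation(0), 0)
  expect_equal(me_gestation(100, term = 280), 0)
  expect_equal(me_gestation(223, term = 280), 0)    # just before the window
  expect_gt(me_gestation(224, term = 280), 0)       # window opens
  expect_equal(me_gestation(280), 0.044 * exp(0.0165 * 280) / 0.2,
               tolerance = 1e-12)
  expect_equal(me_gestation(280), 22.33, tolerance = 1e-2)
})

test_that("gain costs reproduce every printed age-knot cell exactly", {
  tab <- gain_cost_table()
  knots <- c(0, 0.1, 1.5, 3, 4.5, 5.5, 20)
  expected_energy <- list(
    female.crossbred = c(3.4, 4.0, 9.6, 16.5, 23.4, 23.4, 23.4),
    female.indicus   = c(3.4, 3.9, 8.6, 12.9, 16.2, 17.0, 17.0),
    male.crossbred   = c(3.4, 4.0, 9.1, 15.5, 21.8, 25.1, 25.1),
    male.indicus     = c(3.4, 3.9, 7.9, 11.9, 14.8, 18.8, 18.8)
  )
  expected_protein <- list(
    female.crossbred = c(236, 182, 174, 171, 170, 170, 170),
    female.indicus   = c(236, 182, 173, 170, 168, 168, 168),
    male.crossbred   = c(236, 182, 175, 172, 170, 169, 169),
    male.indicus     = c(236, 182, 174, 168, 167, 167, 167)
  )
  for (sex in c("female", "male")) {
    for (cls in c("crossbred", "indicus")) {
      key <- paste(sex, cls, sep = ".")
      ## me_per_kg_gain x kpf recovers the net-energy cell exactly
      expect_equal(me_per_kg_gain(knots, sex, cls) * 0.4,
                   expected_energy[[key]], tolerance = 1e-12)
      ## protein cells via a unit gain without the 2.1 uCP factor
      expect_equal(ucp_gain(knots, sex, cls, gain = 1) / 2.1,
                   expected_protein[[key]], tolerance = 1e-12)
    }
  }
})

test_that("gain costs interpolate linearly and extrapolate flat", {
  expect_equal(me_per_kg_gain(3.0, "female", "crossbred"), 16.5 / 0.4)
  expect_equal(me_per_kg_gain(2.25, "female", "crossbred"),
               mean(c(9.6, 16.5)) / 0.4)
  expect_equal(me_per_kg_gain(20, "male", "indicus"), 18.8 / 0.4)
  expect_equal(me_per_kg_gain(35, "male", "indicus"), 18.8 / 0.4)
  ## non-decreasing in age (energy); non-increasing (protein)
  ages <- seq(0, 25, by = 0.1)
  expect_true(all(diff(me_per_kg_gain(ages, "female", "crossbred")) >= 0))
  expect_true(all(diff(ucp_gain(ages, "female", "crossbred", 1)) <= 0))
})

test_that("uCP for gain multiplies protein content, gain and 2.1", {
  expect_equal(ucp_gain(3, "female", "crossbred", 0.5), 171 * 0.5 * 2.1,
               tolerance = 1e-12)
  expect_equal(ucp_gain(3, "female", "crossbred", 0.5), 179.55)
  expect_equal(ucp_gain(0, "female", "indicus", 0.1), 49.56,
               tolerance = 1e-9)
  expect_equal(ucp_gain(5, "female", "crossbred", 0), 0)
  expect_error(ucp_gain(5, "female", "crossbred", -0.1),
               class = "dairysim_domain_error")
})

test_that("total requirements are additive and ignore negative potential gain", {
  st <- test_state(lactation_month = 0)
  b <- test_breed()
  ## dry, non-pregnant, no gain: total equals maintenance
  r <- total_requirements(st, b, NULL, potential_gain = 0,
                          potential_yield = 0)
  expect_equal(r$me_total, r$me_maintenance)
  expect_equal(r$me_lactation + r$me_activity + r$me_gestation + r$me_gain, 0)
  ## negative potential gain contributes no deposition cost
  rn <- total_requirements(st, b, NULL, potential_gain = -0.5,
                           potential_yield = 0)
  expect_equal(rn$me_gain, 0)
  expect_equal(rn$ucp_gain, 0)

  ## composition of the component formulas for a lactating cow
  st1 <- test_state(lactation_month = 1)
  r1 <- total_requirements(st1, b, NULL, potential_gain = 0.3,
                           potential_yield = 12)
  expect_equal(r1$me_total,
               me_maintenance(415) + me_lactation(12, b$milk_fat, b$kl) +
                 me_per_kg_gain(5.2, "female", "crossbred") * 0.3,
               tolerance = 1e-12)

  ## additivity holds over randomized valid inputs
  set.seed(101)
  for (i in 1:50) {
    st_i <- animal_state(age = runif(1, 0.5, 12),
                         body_weight = runif(1, 60, 600),
                         lactation_month = sample(0:10, 1),
                         gestation_day = sample(c(0, 100, 240, 283), 1))
    r_i <- total_requirements(st_i, b, NULL,
                              potential_gain = runif(1, -0.3, 1),
                              potential_yield = runif(1, 0, 25))
    expect_equal(r_i$me_total,
                 r_i$me_maintenance + r_i$me_lactation + r_i$me_activity +
                   r_i$me_gestation + r_i$me_gain,
                 tolerance = 1e-9)
    expect_equal(r_i$ucp_total,
                 r_i$ucp_maintenance + r_i$ucp_lactation +
                   r_i$ucp_gestation + r_i$ucp_gain,
                 tolerance = 1e-9)
    expect_true(all(unlist(r_i) >= 0))
  }
})
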