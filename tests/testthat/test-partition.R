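part_inputs <- function(state = test_state(), breed = test_breed(),
                        feed = test_ration(), potential_gain = 0.3,
                        potential_milk = 12) {
  req <- total_requirements(state, breed, NULL,
                            potential_gain = potential_gain,
                            potential_yield = potential_milk)
  list(req = req, state = state, breed = breed, feed = feed,
       potential_milk = potential_milk)
}

test_that("MEI at exactly maintenance in mid lactation gives no milk and no gain", {
  p <- part_inputs(state = test_state(lactation_month = 5))
  out <- partition_step(p$req$me_maintenance, p$req, p$state, p$breed,
                        p$feed, p$potential_milk)
  expect_equal(out$actual_milk, 0)
  expect_equal(out$actual_gain, 0)
  expect_equal(out$mobilized_bw, 0)
  expect_equal(as.character(out$lactation_stage), "mid")
})

test_that("mid-lactation surplus splits 85/15 between milk and gain on forage diets", {
  p <- part_inputs(state = test_state(lactation_month = 5),
                   potential_milk = 20)
  S <- 20  # surplus small enough that the potential-milk energy cap is slack
  mei <- p$req$me_maintenance + S
  out <- partition_step(mei, p$req, p$state, p$breed, p$feed, 20)
  milk_cost <- me_per_kg_milk(p$breed$milk_fat, p$breed$kl)
  expect_equal(out$me_to_milk, 0.85 * S, tolerance = 1e-9)
  expect_equal(out$me_to_gain, 0.15 * S, tolerance = 1e-9)
  expect_equal(out$actual_milk, 0.85 * S / milk_cost, tolerance = 1e-9)
  ## with concentrate in the diet the mid fraction rises to 0.88
  outc <- partition_step(mei, p$req, p$state, p$breed,
                         test_ration(contains_concentrate = TRUE), 20)
  expect_equal(outc$me_to_milk, 0.88 * S, tolerance = 1e-9)
  ## early-lactation fraction is 1.0 for both diet types
  expect_equal(stage_fractions(TRUE)[["early"]], 1)
  expect_equal(stage_fractions(FALSE)[["early"]], 1)
})

test_that("mid/late surplus beyond the potential-milk cost spills to gain", {
  p <- part_inputs(state = test_state(lactation_month = 5),
                   potential_milk = 2)
  milk_cost <- me_per_kg_milk(p$breed$milk_fat, p$breed$kl)
  mei <- p$req$me_maintenance + 60
  out <- partition_step(mei, p$req, p$state, p$breed, p$feed, 2)
  expect_equal(out$actual_milk, 2, tolerance = 1e-9)  # capped at potential
  expect_equal(out$me_to_gain, 60 - 2 * milk_cost, tolerance = 1e-9)
  expect_gt(out$actual_gain, 0)
})

test_that("early-lactation mobilization tops milk up to 60% of potential within the cap", {
  st <- test_state(lactation_month = 1, body_weight = 400)
  p <- part_inputs(state = st, potential_milk = 15)
  milk_cost <- me_per_kg_milk(p$breed$milk_fat, p$breed$kl)
  ## small surplus: MEI-funded milk far below the 60% target
  mei <- p$req$me_maintenance + 5
  out <- partition_step(mei, p$req, st, p$breed, p$feed, 15)
  expect_lte(out$mobilized_bw, 0.0023 * 400 + 1e-12)
  expect_gt(out$mobilized_bw, 0)
  expect_lte(out$actual_milk, 0.6 * 15 + 1e-9)
  expect_equal(out$actual_gain, -out$mobilized_bw, tolerance = 1e-9)

  ## plentiful MEI: milk above the 60% target, no mobilization at all
  mei2 <- p$req$me_maintenance + 0.7 * 15 * milk_cost
  out2 <- partition_step(mei2, p$req, st, p$breed, p$feed, 15)
  expect_equal(out2$mobilized_bw, 0)
  expect_equal(out2$actual_milk, 0.7 * 15, tolerance = 1e-9)

  ## MEI-funded milk is never cut back below what intake can pay for
  expect_gte(out2$actual_milk, 0.6 * 15)
})

test_that("no reserves are mobilized for milk after month 3", {
  for (month in c(4, 7, 9, 10)) {
    st <- test_state(lactation_month = month)
    p <- part_inputs(state = st, potential_milk = 15)
    ## MEI above maintenance: any mobilization would be milk-driven
    out <- partition_step(p$req$me_maintenance + 10, p$req, st, p$breed,
                          p$feed, 15)
    expect_equal(out$mobilized_bw, 0)
  }
  ## below maintenance in mid lactation: survival mobilization only, no milk
  st <- test_state(lactation_month = 5)
  p <- part_inputs(state = st, potential_milk = 15)
  out <- partition_step(p$req$me_maintenance - 10, p$req, st, p$breed,
                        p$feed, 15)
  expect_equal(out$actual_milk, 0)
  expect_gt(out$mobilized_bw, 0)
})

test_that("survival and milk mobilization share the daily 0.23% cap", {
  st <- test_state(lactation_month = 1, body_weight = 400)
  p <- part_inputs(state = st, potential_milk = 20)
  out <- partition_step(0, p$req, st, p$breed, p$feed, 20)
  expect_equal(out$mobilized_bw, 0.0023 * 400, tolerance = 1e-12)
  expect_equal(out$actual_gain, -0.0023 * 400, tolerance = 1e-12)
  expect_equal(out$actual_milk, 0)  # reserves all consumed by survival
  expect_error(partition_step(-1, p$req, st, p$breed, p$feed, 20),
               class = "dairysim_domain_error")
})

test_that("energy closes exactly for randomized inputs", {
  set.seed(7)
  for (i in 1:1000) {
    breed <- test_breed(species_class = sample(c("crossbred", "indicus"), 1),
                        milk_fat = runif(1, 35, 55))
    st <- test_state(age = runif(1, 1.5, 12),
                     body_weight = runif(1, 150, 550),
                     lactation_month = sample(0:10, 1),
                     gestation_day = sample(c(0, 250), 1))
    feed <- test_ration(contains_concentrate = runif(1) < 0.5)
    pot_milk <- if (st$lactation_month > 0) runif(1, 0, 25) else 0
    req <- total_requirements(st, breed, NULL,
                              potential_gain = runif(1, 0, 1),
                              potential_yield = pot_milk)
    mei <- runif(1, 0, 1.6) * req$me_total
    out <- partition_step(mei, req, st, breed, feed, pot_milk)
    expect_equal(out$mei + out$mobilized_me,
                 out$me_to_maintenance + out$me_to_activity +
                   out$me_to_gestation + out$me_to_milk + out$me_to_gain,
                 tolerance = 1e-9)
    expect_lte(out$mobilized_bw, 0.0023 * st$body_weight + 1e-12)
    expect_lte(out$actual_milk, pot_milk + 1e-9)
    expect_gte(out$actual_milk, 0)
    if (out$mobilized_bw > 1e-12) {
      expect_true(as.character(out$lactation_stage) == "early" ||
                    mei < req$me_maintenance + req$me_activity +
                      req$me_gestation)
    }
  }
})

test_that("actual milk is non-decreasing in MEI, all else fixed", {
  for (month in c(1, 5)) {
    st <- test_state(lactation_month = month)
    p <- part_inputs(state = st, potential_milk = 18)
    meis <- seq(0, 2 * p$req$me_total, length.out = 120)
    milk <- vapply(meis, function(m)
      partition_step(m, p$req, st, p$breed, p$feed, 18)$actual_milk,
      numeric(1))
    expect_true(all(diff(milk) >= -1e-9))
  }
})
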