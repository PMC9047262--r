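test_that("pigs at risk subtracts half the mortality", {
  expect_equal(pigs_at_risk(1000, 40), 980)
  expect_equal(pigs_at_risk(500, 0), 500)
  expect_equal(pigs_at_risk(100, 3), 98.5) # fractional, kept unrounded
  expect_error(pigs_at_risk(10, 11), "exceed")
  expect_error(pigs_at_risk(-1, 0), "non-negative")
})

test_that("time at risk follows the flow type", {
  co <- mini_cohorts()
  tau <- time_at_risk(co)
  expect_equal(tau, c(23, 23, 52, 112))
  broken <- co
  broken$cycle_start_date[1] <- NA
  expect_error(time_at_risk(broken), "cycle_start_date")
})

test_that("route mass formulas match hand arithmetic", {
  feed_rec <- tibble::tibble(
    cohort_id = "X", pig_type = "nursery", aai = "a", reason = "prevention",
    g_per_tonne = 400, pct_fed = 1)
  expect_equal(feed_mass(feed_rec, 100, 1000)$total_mg, 40e6)
  feed_rec$g_per_tonne <- 0
  expect_equal(feed_mass(feed_rec, 100, 1000)$total_mg, 0)
  feed_rec$g_per_tonne <- 250
  feed_rec$pct_fed <- 0.5
  expect_equal(feed_mass(feed_rec, 137.2, 980)$total_mg, 16807000)
  expect_equal(feed_mass(feed_rec, 137.2, 980)$pigs_exposed, 490)

  water_rec <- tibble::tibble(
    cohort_id = "X", pig_type = "nursery", aai = "a", reason = "treatment",
    g_per_litre = 0.5, duration = 5, pct_exposed = 1)
  expect_equal(water_mass(water_rec, 3.202, 100)$total_mg, 800500)
  water_rec$duration <- 0
  expect_equal(water_mass(water_rec, 3.202, 100)$total_mg, 0)
  sow_water <- tibble::tibble(
    cohort_id = "X", pig_type = "sows", aai = "a", reason = "treatment",
    g_per_litre = 1, duration = 3, pct_exposed = 1)
  expect_equal(water_mass(sow_water, 18, 30)$total_mg, 1620000)

  inj_rec <- tibble::tibble(
    cohort_id = "X", pig_type = "sows", aai = "a", reason = "treatment",
    concentration = 300, volume_per_pig_per_day = 1, duration = 3,
    pct_exposed = 1)
  expect_equal(injection_mass(inj_rec, 100)$total_mg, 90000)
  inj_rec$volume_per_pig_per_day <- 0
  expect_equal(injection_mass(inj_rec, 100)$total_mg, 0)
  litterwide <- tibble::tibble(
    cohort_id = "X", pig_type = "suckling", aai = "a",
    reason = "prevention", concentration = 50,
    volume_per_pig_per_day = 1, duration = 1, pct_exposed = 0.05)
  expect_equal(injection_mass(litterwide, 9994)$total_mg, 24985)

  creep_rec <- tibble::tibble(
    cohort_id = "X", aai = "a", reason = "prevention", g_per_tonne = 500,
    pct_piglets_fed = 1, pct_wasted = 0.2)
  expect_equal(creep_mass(creep_rec, 400, 100)$total_mg, 16000)
  creep_rec$pct_wasted <- 1 - 1e-15
  expect_equal(creep_mass(creep_rec, 400, 100)$total_mg, 0,
               tolerance = 1e-9)
})

test_that("creep mass without wastage equals the feed-route formula", {
  set.seed(5)
  for (rep in 1:10) {
    dose <- runif(1, 10, 800)
    intake_g <- runif(1, 50, 600)
    pigs <- runif(1, 50, 900)
    pct <- runif(1)
    creep_rec <- tibble::tibble(
      cohort_id = "X", aai = "a", reason = "prevention",
      g_per_tonne = dose, pct_piglets_fed = pct, pct_wasted = 0)
    feed_rec <- tibble::tibble(
      cohort_id = "X", pig_type = "suckling", aai = "a",
      reason = "prevention", g_per_tonne = dose, pct_fed = pct)
    expect_equal(creep_mass(creep_rec, intake_g, pigs)$total_mg,
                 feed_mass(feed_rec, intake_g / 1000, pigs)$total_mg)
  }
})

test_that("masses scale linearly in dose, intake, pigs and exposure", {
  base <- tibble::tibble(
    cohort_id = "X", pig_type = "nursery", aai = "a", reason = "prevention",
    g_per_tonne = 300, pct_fed = 0.5)
  m0 <- feed_mass(base, 40, 200)$total_mg
  doubled_dose <- dplyr::mutate(base, g_per_tonne = 600)
  expect_equal(feed_mass(doubled_dose, 40, 200)$total_mg, 2 * m0)
  expect_equal(feed_mass(base, 80, 200)$total_mg, 2 * m0)
  expect_equal(feed_mass(base, 40, 400)$total_mg, 2 * m0)
  expect_equal(feed_mass(dplyr::mutate(base, pct_fed = 1), 40, 200)$total_mg,
               2 * m0)
})

test_that("study-level exposure computes every record against its cohort", {
  study <- mini_study()
  ex <- compute_exposure(study)
  expect_equal(nrow(ex), nrow(study$feed) + nrow(study$creep) +
                 nrow(study$water) + nrow(study$injection))

  # sow in-feed: 5966 g/day x 14 d, 29 sows at risk
  sow_feed <- ex[ex$pig_type == "sows" & ex$route == "feed", ]
  expect_equal(sow_feed$total_mg, 500 * (5966 * 14 / 1000 / 1000) * 29 * 1000)

  # sow injection: 300 mg/mL x 2 mL x 3 d x 29 x 5%
  sow_inj <- ex[ex$pig_type == "sows" & ex$route == "injection", ]
  expect_equal(sow_inj$total_mg, 300 * 2 * 3 * 29 * 0.05)

  # creep: quadratic litter model at 14 d, litter of 11, 20% wasted
  creep_g <- (20 * 14 + 6 * 14^2) / 11
  suck <- ex[ex$route == "creep", ]
  expect_equal(suck$total_mg, 600 * creep_g / 1e6 * 380 * 0.8 * 1000)

  # per-ingredient sums over routes equal the cohort all-routes total
  f01 <- ex[ex$cohort_id == "F01", ]
  expect_equal(sum(f01$total_mg),
               sow_feed$total_mg + sow_inj$total_mg + suck$total_mg)
})

test_that("single-stage strata and water intake feed the mass chain", {
  study <- mini_study()
  ex <- compute_exposure(study)
  # single nursery cohort: its ADG is both quartiles, tie -> "average"
  curves <- read_intake_curves()
  fpp <- cumulative_feed_per_pig(curves$curves$nursery$average, 28)
  n_feed <- ex[ex$pig_type == "nursery" & ex$route == "feed", ]
  expect_equal(n_feed$total_mg, 550 * fpp / 1000 * 490 * 1000)

  mean_feed <- cumulative_feed_per_pig(curves$curves$nursery$average, 52) / 52
  dw <- water_intake_per_day(mean_feed)
  n_water <- ex[ex$route == "water", ]
  expect_equal(n_water$total_mg, 0.4 * dw * 5 * 490 * 1000)
})
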