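test_that("sow daily feed is gross allowance net of wastage", {
  expect_equal(sow_daily_feed(), 5966)
  expect_equal(sow_daily_feed(sow_feed_params(1000, 0)), 1000)
  expect_equal(sow_daily_feed(sow_feed_params(1000, 0.5)), 500)
})

test_that("water intake is affine and strictly increasing in feed", {
  expect_equal(water_intake_per_day(0), 0.149)
  expect_equal(water_intake_per_day(1), 3.202)
  expect_equal(water_intake_per_day(0.5), 1.6755)
  feeds <- seq(0, 3, by = 0.25)
  w <- water_intake_per_day(feeds)
  expect_true(all(diff(w) > 0))
  # affine: second differences vanish
  expect_equal(diff(w, differences = 2), rep(0, length(w) - 2))
  expect_error(water_intake_per_day(-0.1), "non-negative")
})

test_that("average daily gain is elementary and guarded", {
  expect_equal(adg(6, 27, 50), 0.42)
  expect_equal(adg(20, 20, 10), 0)
  expect_equal(adg(25, 120, 112), 95 / 112) # 0.848 kg/day
  expect_error(adg(10, 20, 0), "positive")
})

test_that("performance strata split at interpolated quartiles", {
  all_adg <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  # (n + 1) p interpolation: q25 = 0.35, q75 = 0.65
  expect_equal(assign_stratum(min(all_adg), all_adg), "low")
  expect_equal(assign_stratum(0.5, all_adg), "average")
  expect_equal(assign_stratum(0.65, all_adg), "average") # tie at q75
  expect_equal(assign_stratum(0.7, all_adg), "high")
  # thresholds landing on data values: ties fall to average
  adg7 <- 1:7 # q25 = 2, q75 = 6
  expect_equal(assign_stratum(c(1, 2, 4, 6, 7), adg7),
               c("low", "average", "average", "average", "high"))
  expect_error(assign_stratum(0.5, numeric(0)), "at least one")
})

test_that("closed-form cumulative feed matches elementary areas", {
  const <- intake_curve(1)
  expect_equal(cumulative_feed_per_pig(const, 10), 10)
  # linear 0.2 -> 1.2 kg/day over 50 days: trapezoid area 35
  linear <- intake_curve(c(0.2, 0.02))
  expect_equal(cumulative_feed_per_pig(linear, 50), 35)
  expect_equal(cumulative_feed_per_pig(linear, 0), 0)
  expect_error(cumulative_feed_per_pig(intake_curve(c(-1, 0.001)), 10),
               "negative")
})

test_that("polynomial integral equals adaptive quadrature to 1e-9", {
  curves <- read_intake_curves()
  for (stage in names(curves$curves)) {
    for (stratum in names(curves$curves[[stage]])) {
      curve <- curves$curves[[stage]][[stratum]]
      for (days in c(7, 28, 52, 112)) {
        closed <- cumulative_feed_per_pig(curve, days)
        quad <- stats::integrate(
          function(x) poly_eval_oracle(curve$coefficients, x),
          0, days, rel.tol = 1e-12)$value
        expect_equal(closed, quad, tolerance = 1e-9)
        expect_gte(closed, 0)
      }
      # non-decreasing in days on feed
      vals <- vapply(seq(0, 90, by = 5), cumulative_feed_per_pig,
                     numeric(1), curve = curve)
      expect_true(all(diff(vals) >= 0))
    }
  }
})

test_that("fitting recovers an exactly polynomial intake curve", {
  days <- c(0, 10, 20, 30, 40, 50)
  truth <- c(0.3, 0.015, 1e-4)
  fit <- fit_intake_curve(days, poly_eval_oracle(truth, days), degree = 2)
  expect_equal(fit$coefficients, truth, tolerance = 1e-8)
})

test_that("creep intake is zero at zero duration and monotone", {
  model <- creep_intake_model()
  expect_equal(creep_feed_per_piglet(21, 21, model), 0)
  # linear 50 g/litter/day for 7 days -> 350/11 per piglet
  lin <- creep_intake_model(coefficients = c(0, 50))
  expect_equal(creep_feed_per_piglet(14, 21, lin), 350 / 11)
  expect_gte(creep_feed_per_piglet(10, 20, model),
             creep_feed_per_piglet(15, 20, model))
  expect_error(creep_feed_per_piglet(22, 21, model), ">=")
  expect_error(creep_intake_model(coefficients = c(100, -10)),
               "non-decreasing")
})
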