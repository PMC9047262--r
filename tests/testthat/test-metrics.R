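test_that("core metric arithmetic is exact", {
  expect_equal(mg_per_kg_biomass(0, 100, 11.5), 0)
  expect_equal(n_ddd(10000, 10, 10), 100)
  expect_equal(n_ddd(0, 10, 10), 0)
  expect_equal(ddd_per_pig(100, 50), 2)
  expect_equal(ddd_per_pig(0, 50), 0)
  expect_equal(ddd_rate(1, 1000), 1)
  expect_error(mg_per_kg_biomass(10, 0, 11.5), "positive")
  expect_error(ddd_per_pig(10, 0), "positive")
  expect_error(ddd_rate(10, 0), "positive")
})

test_that("doubling the standard dose halves the dose count", {
  set.seed(3)
  for (rep in 1:10) {
    mg <- runif(1, 1, 1e7)
    ddd <- runif(1, 1, 40)
    w <- runif(1, 4, 240)
    expect_equal(n_ddd(mg, 2 * ddd, w), n_ddd(mg, ddd, w) / 2)
  }
})

test_that("rate times time recovers doses per pig exactly", {
  set.seed(4)
  dpp <- runif(20, 0, 40)
  tau <- sample(c(23, 52, 112), 20, replace = TRUE)
  expect_equal(ddd_rate(dpp, tau) * tau / 1000, dpp, tolerance = 1e-12)
})

test_that("missing registry entries error naming the ingredient", {
  study <- mini_study()
  ex <- compute_exposure(study)
  reg <- read_ddd_registry()
  expect_error(
    build_metrics_tables(study, ex, registry = reg[reg$aai != "lincomycin", ]),
    "lincomycin")
  # long-acting formulations are distinct keys
  ex_la <- ex
  ex_la$long_acting[ex_la$aai == "lincomycin"] <- TRUE
  expect_error(build_metrics_tables(study, ex_la, registry = reg),
               "lincomycin \\(long-acting\\)")
})

test_that("percent of herds using is counted against the stage denominator", {
  study <- mini_study()
  ex <- compute_exposure(study)
  expect_equal(percent_herds_using(ex, study, "sows", "feed")$percent, 100)
  expect_equal(percent_herds_using(ex, study, "nursery", "injection")$percent, 0)
  all_n <- percent_herds_using(ex, study, "nursery")
  expect_equal(all_n$n_herds, 1)
  expect_equal(all_n$n_total, 1)
  # zero-mass exposures do not make a herd a user
  ex0 <- ex
  ex0$total_mg <- 0
  expect_equal(percent_herds_using(ex0, study, "sows")$percent, 0)
  expect_error(percent_herds_using(ex, study, "sows"[0]), "pig type")
})

test_that("all-routes rows are sums and mg/kg is additive over routes", {
  g <- generate_study(small_config(seed = 21))
  m <- build_metrics_tables(g$study, compute_exposure(g$study))
  br <- m$by_route
  for (pt in unique(br$pig_type)) {
    routes <- br[br$pig_type == pt & br$route != "all_routes", ]
    all_row <- br[br$pig_type == pt & br$route == "all_routes", ]
    expect_equal(all_row$total_g, sum(routes$total_g))
    expect_equal(all_row$mg_per_kg_biomass, sum(routes$mg_per_kg_biomass))
    expect_equal(all_row$ddd_per_pig, sum(routes$ddd_per_pig))
  }
  # by-ingredient masses sum to the route mass
  bi <- m$by_ingredient
  agg <- dplyr::summarise(
    dplyr::group_by(bi, pig_type, route),
    total_g = sum(total_g), .groups = "drop")
  joined <- dplyr::inner_join(agg, br, by = c("pig_type", "route"))
  expect_equal(joined$total_g.x, joined$total_g.y)
})

test_that("metrics are invariant to doubling herd size and mass", {
  study <- mini_study()
  ex <- compute_exposure(study)
  m1 <- build_metrics_tables(study, ex, times = reference_times())

  doubled <- study
  doubled$cohorts$n_start_or_entered <- 2 * doubled$cohorts$n_start_or_entered
  doubled$cohorts$n_deaths <- 2 * doubled$cohorts$n_deaths
  ex2 <- compute_exposure(doubled)
  expect_equal(ex2$total_mg, 2 * ex$total_mg)
  m2 <- build_metrics_tables(doubled, ex2, times = reference_times())
  expect_equal(m2$by_route$mg_per_kg_biomass, m1$by_route$mg_per_kg_biomass)
  expect_equal(m2$by_route$ddd_per_pig, m1$by_route$ddd_per_pig)
  expect_equal(m2$by_route$ddd_rate, m1$by_route$ddd_rate)
})

test_that("pooled metrics equal per-herd metrics for a single cohort", {
  study <- mini_study()
  ex <- compute_exposure(study)
  m <- build_metrics_tables(study, ex, mode = "per_herd")
  # G01 is the only grower-finisher herd and its cohort time (112 d) is
  # the stage median, so pooled and per-herd rows must agree
  pooled <- m$by_route[m$by_route$pig_type == "grower_finisher" &
                         m$by_route$route == "feed", ]
  herd <- m$per_herd[m$per_herd$cohort_id == "G01" &
                       m$per_herd$route == "feed", ]
  expect_equal(pooled$mg_per_kg_biomass, herd$mg_per_kg_biomass)
  expect_equal(pooled$ddd_per_pig, herd$ddd_per_pig)
  expect_equal(pooled$ddd_rate, herd$ddd_rate)
})

test_that("creep is reported under the feed route for suckling pigs", {
  study <- mini_study()
  m <- build_metrics_tables(study, compute_exposure(study))
  suck <- m$by_route[m$by_route$pig_type == "suckling", ]
  expect_true("feed" %in% suck$route)
  expect_false("creep" %in% suck$route)
})
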