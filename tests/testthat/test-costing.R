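# Costing: unit prices, medication weighting, productivity valuation,
# perspective aggregation, indexing and conversion.

test_that("contact, inpatient and travel costs are quantity times price", {
  p <- unit_price_table()
  five_gp <- cost_contacts(zero_panel(gp_visits = 5), p)
  expect_equal(five_gp$gp_internist, 5 * 20.92) # 104.60
  two_days <- cost_contacts(zero_panel(inpatient_mental_days = 2), p)
  expect_equal(two_days$inpatient, 2 * 335.52) # 671.04
  km <- cost_contacts(zero_panel(travel_km = 100), p)
  expect_equal(km$travel, 30.00)
  expect_error(cost_contacts(zero_panel(gp_visits = -1), p), "negative")
  expect_error(cost_contacts(data.frame(gp_visits = 1), p), "lacks columns")
})

test_that("medication pricing weights package prices by statutory share", {
  same <- data.frame(price_statutory = rep(30, 3),
                     price_private = rep(30, 3), ddd = rep(30, 3))
  expect_equal(cost_medication(same, 30), 30)
  expect_equal(cost_medication(same, 0), 0)

  mixed <- data.frame(price_statutory = c(20, 40, 60),
                      price_private = c(25, 50, 80),
                      ddd = c(50, 100, 100))
  # hand-computed weighted mean of per-day prices at share 0.89
  per_day <- mean(c((0.89 * 20 + 0.11 * 25) / 50,
                    (0.89 * 40 + 0.11 * 50) / 100,
                    (0.89 * 60 + 0.11 * 80) / 100))
  expect_equal(cost_medication(mixed, 90, 0.89), per_day * 90)
  bad <- transform(mixed, ddd = c(0, 100, 100))
  expect_error(cost_medication(bad, 10), "zero daily dose")
})

test_that("productivity losses follow the human capital approach", {
  expect_equal(value_absenteeism(10, 100), 1000)
  expect_equal(value_absenteeism(0, 100), 0)
  expect_equal(value_presenteeism(5, 10, 120), 0)   # fully efficient
  expect_equal(value_presenteeism(5, 6, 120), 240)  # 5 x 0.4 x 120
  expect_equal(value_presenteeism(1, 0, 80), 80)    # total inefficiency
  expect_error(value_presenteeism(1, 11, 80), "outside")
  expect_equal(value_unpaid(10), 183.30)
  expect_equal(value_unpaid(0), 0)
})

test_that("perspective totals match the published composition", {
  ctrl <- reference_cost_means("control")
  expect_equal(aggregate_costs(ctrl, "health_care"), 768)
  expect_equal(aggregate_costs(ctrl, "societal"), sum(ctrl))
  zeros <- setNames(rep(0, length(cost_categories())), cost_categories())
  expect_equal(aggregate_costs(zeros, "societal"), 0)
  expect_equal(aggregate_costs(zeros, "health_care"), 0)
  expect_error(aggregate_costs(c(banana = 1), "societal"), "unknown")
})

test_that("societal totals dominate health-care totals on any breakdown", {
  set.seed(14)
  for (i in 1:20) {
    bd <- setNames(as.list(rexp(length(cost_categories()), 1 / 100)),
                   cost_categories())
    bd <- as.data.frame(bd)
    expect_gte(aggregate_costs(bd, "societal"),
               aggregate_costs(bd, "health_care"))
  }
})

test_that("costing is linear in quantities", {
  p <- unit_price_table()
  set.seed(15)
  panel <- zero_panel(3,
                      gp_visits = rpois(3, 4), internist_visits = rpois(3, 1),
                      psychotherapist_sessions = rpois(3, 2),
                      inpatient_mental_days = c(0, 2, 5),
                      travel_km = runif(3, 0, 40),
                      informal_care_hours = runif(3, 0, 30),
                      absent_days = c(0, 3, 10),
                      presenteeism_days = c(1, 0, 4),
                      efficiency_rating = c(4, 7, 9))
  wage <- c(90, 120, 150)
  base <- panel_cost_breakdown(panel, p, wage)
  scaled <- panel
  qcols <- setdiff(prevcea:::panel_fields(), "efficiency_rating")
  scaled[qcols] <- 2.5 * scaled[qcols]
  expect_equal(as.matrix(panel_cost_breakdown(scaled, p, wage)),
               2.5 * as.matrix(base), tolerance = 1e-12)
})

test_that("indexing and currency conversion match printed anchors", {
  expect_equal(index_and_convert(100)$eur, 104)
  # program cost EUR 299 converts to GBP 254 after rounding
  expect_equal(euro_round(index_and_convert(299, index_factor = 1)$gbp), 254)
  expect_equal(index_and_convert(20000, index_factor = 1)$gbp, 17000)
  expect_error(index_and_convert(-1), "amount")
})
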