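test_that("acute event costs pool by the sex-specific event mix", {
  comp <- c(mi = 1996, angina = 1237, arrest = 1026)
  mix <- list(male = c(mi = 0.35, angina = 0.55, arrest = 0.10),
              female = c(mi = 0.20, angina = 0.70, arrest = 0.10))
  expect_equal(pooled_incident_cost(comp, mix, "male"), 1481.55)
  expect_equal(pooled_incident_cost(comp, mix, "female"), 1367.70)
  expect_equal(pooled_incident_cost(comp, c(mi = 1, angina = 0, arrest = 0)),
               1996)
  expect_error(pooled_incident_cost(comp, c(mi = 0.5, angina = 0.4,
                                            arrest = 0.05)), "sum to 1")
})

test_that("discounting is year-1-undiscounted and monotone in the rate", {
  expect_equal(discount(c(100, 100), 0), c(100, 100))
  expect_equal(discount(c(100, 100), 0.03), c(100, 100 / 1.03))
  s <- rep(50, 30)
  expect_lt(sum(discount(s, 0.06)), sum(discount(s, 0.03)))
  expect_lt(sum(discount(s, 0.03)), sum(discount(s, 0)))
  expect_error(discount(s, -0.01), "non-negative")
})

test_that("government stream carries only recurrent categories past year 5", {
  sched <- data.frame(
    category = rep(c("strategy_development", "human_resources",
                     "administration"), each = 5),
    year = rep(1:5, 3),
    value = c(5e5, 0, 0, 0, 0, rep(2e5, 5), rep(1e5, 5)))
  g <- government_cost_stream(sched, horizon = 12)
  expect_equal(g$cost[1], 5e5 + 2e5 + 1e5)
  expect_equal(g$cost[6:12], rep(3e5, 7))
  # one-off-only schedule goes to zero after year 1
  one <- sched[sched$category == "strategy_development", ]
  g1 <- government_cost_stream(one, 10, recurrent = character())
  expect_equal(g1$cost, c(5e5, rep(0, 9)))
  # constant recurrent cost accumulates linearly undiscounted
  hr <- sched[sched$category == "human_resources", ]
  expect_equal(sum(government_cost_stream(hr, 10,
                                          recurrent = "human_resources")$cost),
               10 * 2e5)
  # monitoring uplift scales the human-resources category only
  gu <- government_cost_stream(sched, 12,
                               uplift = c(human_resources = 1.5))
  expect_equal(gu$cost[6], 1e5 + 1.5 * 2e5)
  expect_error(government_cost_stream(one, 10), "missing category")
})

test_that("industry stream is a lump plus an annual fraction", {
  s <- industry_cost_stream(25000, 99, 0.01, horizon = 10)
  expect_equal(s$cost[1], 2475000)
  expect_equal(s$cost[2], 24750)
  expect_equal(s$cost[10], 24750)
  expect_equal(industry_cost_stream(25000, 0, 0.01, 5)$cost, rep(0, 5))
  # conversion multiplier scales the whole stream
  s2 <- industry_cost_stream(25000, 99, 0.01, 10, multiplier = 1.79)
  expect_equal(s2$cost, s$cost * 1.79)
})

test_that("healthcare stream prices averted prevalence directly", {
  # hand-built two-cycle run: the intervention only removes 1000 prevalent
  # case-years, with no survival or incidence change
  mk <- function(prev_py) {
    list(alive = matrix(1, 2, 1), deaths = matrix(0, 2, 1),
         ihd_deaths = matrix(0, 2, 1), events = matrix(0, 2, 1),
         ly = matrix(1, 2, 1), haly = matrix(1, 2, 1),
         prev_py = matrix(prev_py, 2, 1),
         age = matrix(c(20L, 21L), 2, 1), entry_ages = 20L, entry_pop = 1)
  }
  rt <- data.frame(sex = "female", age = 20:100, other_pc = 50)
  run <- structure(list(by_sex = list(
    female = list(reference = mk(1000), intervention = mk(500), rates = rt),
    male = list(reference = mk(0), intervention = mk(0), rates = rt)),
    entry_ages = 20L, n_cycles = 2L), class = "pmslt_run")
  costs <- fixture_bundle()$costs
  hc <- healthcare_cost_stream(run, costs)
  expect_equal(sum(hc$ihd_prevalent), -1000 * 336)
  expect_equal(sum(hc$other), 0)
  expect_equal(sum(hc$total), -1000 * 336)
})

test_that("added life years make total savings smaller than IHD savings", {
  res <- fixture_result()
  s <- res$economics$summary
  for (h in c("5y", "10y", "lifetime")) {
    ihd <- s$value[s$horizon == h & s$measure == "ihd_healthcare_cost"]
    tot <- s$value[s$horizon == h & s$measure == "total_healthcare_cost"]
    expect_lt(ihd, 0)
    expect_lt(abs(tot), abs(ihd))
  }
})

test_that("a zero-effect run has a zero healthcare stream", {
  res <- fixture_null_result()
  st <- res$economics$streams
  expect_true(all(st$ihd_healthcare == 0))
  expect_true(all(st$other_healthcare == 0))
})

test_that("cost-effectiveness classification follows the WHO thresholds", {
  ce <- cost_effectiveness(-12.5e6, 1175)
  expect_true(ce$cost_saving)
  expect_identical(ce$classification, "cost-saving")

  ce <- cost_effectiveness(20.4e6, 154725, implementation_cost = 20.4e6)
  expect_equal(ce$icer_implementation_only, 131.85, tolerance = 1e-3)
  expect_identical(ce$classification, "very cost-effective")

  ce <- cost_effectiveness(1e6, 100, gov_cost = 2.45e6,
                           healthcare_savings = 19.6e6)
  expect_equal(ce$roi, 8, tolerance = 1e-6)

  # boundaries are half-open
  expect_identical(cost_effectiveness(1720, 1)$classification,
                   "cost-effective")
  expect_identical(cost_effectiveness(1719.99, 1)$classification,
                   "very cost-effective")
  expect_identical(cost_effectiveness(5161, 1)$classification,
                   "not cost-effective")
  expect_identical(cost_effectiveness(10, 0)$classification, "undefined")
})

test_that("net cost equals the sum of its components to the cent", {
  res <- fixture_result()
  s <- res$economics$summary
  for (h in c("5y", "10y", "lifetime")) {
    v <- function(m) s$value[s$horizon == h & s$measure == m]
    expect_lt(abs(v("net_cost") - (v("total_healthcare_cost") +
                                     v("government_cost") +
                                     v("industry_cost"))), 0.01)
    expect_equal(v("implementation_cost"),
                 v("government_cost") + v("industry_cost"))
  }
})

test_that("the ICER is invariant to population scale", {
  b <- fixture_bundle()
  bk <- b
  bk$rates$population <- b$rates$population * 5
  # implementation costs do not scale with population, so compare the
  # healthcare-only ICER component: halys and healthcare costs both scale
  r1 <- run_analysis(b)$economics$summary
  rk <- run_analysis(bk)$economics$summary
  v <- function(s, m) s$value[s$horizon == "lifetime" & s$measure == m]
  icer_hc1 <- v(r1, "total_healthcare_cost") / v(r1, "halys_gained")
  icer_hck <- v(rk, "total_healthcare_cost") / v(rk, "halys_gained")
  expect_equal(icer_hc1, icer_hck, tolerance = 1e-9)
})

test_that("the product share helper returns a percentage", {
  expect_equal(itfa_product_share(99, 5668), 100 * 99 / 5668)
  expect_error(itfa_product_share(1, 0))
})
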