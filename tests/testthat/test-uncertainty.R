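test_that("draws are reproducible from seed and iteration", {
  b <- fixture_bundle()
  cfg <- psa_config(n_iterations = 10, seed = 11)
  d1 <- draw_inputs(b, cfg, 3)
  d2 <- draw_inputs(b, cfg, 3)
  expect_identical(d1$exposure$mean, d2$exposure$mean)
  expect_identical(d1$rr$rr, d2$rr$rr)
  expect_identical(d1$costs$gov_schedule$value, d2$costs$gov_schedule$value)
  d3 <- draw_inputs(b, cfg, 4)
  expect_false(identical(d1$exposure$mean, d3$exposure$mean))
})

test_that("with all variation flags off the central bundle is returned", {
  b <- fixture_bundle()
  cfg <- psa_config(vary_intake = FALSE, vary_rr = FALSE,
                    vary_healthcare_costs = FALSE,
                    vary_implementation_costs = FALSE)
  d <- draw_inputs(b, cfg, 1)
  attr(d, "truncated_draws") <- NULL
  expect_equal(d, b)
})

test_that("drawn relative risks and intake means are centred on the inputs", {
  b <- fixture_bundle()
  cfg <- psa_config(seed = 5)
  rr_draws <- intake_draws <- numeric(2000)
  for (it in 1:2000) {
    d <- draw_inputs(b, cfg, it)
    rr_draws[it] <- d$rr$rr[1]
    intake_draws[it] <- d$exposure$mean[1]
  }
  expect_lt(abs(mean(rr_draws) - b$rr$rr[1]) / b$rr$rr[1], 0.01)
  expect_lt(abs(mean(intake_draws) - b$exposure$mean[1]) /
              b$exposure$mean[1], 0.02)
})

test_that("the nearest-rank percentile matches a sorted-array reference", {
  set.seed(42)
  x <- rnorm(2000)
  xs <- sort(x)
  for (p in c(0.025, 0.5, 0.975, 0.001, 1)) {
    expect_identical(nearest_rank_percentile(x, p), xs[ceiling(p * 2000)])
  }
  # ties resolve to the lower index of the stable sort
  expect_identical(nearest_rank_percentile(c(2, 1, 1, 3), 0.5), 1)
})

test_that("a degenerate PSA collapses onto the deterministic run", {
  b <- fixture_bundle()
  b$exposure$sd <- 0          # point-mass intakes
  b$rr$log_sd <- 0
  cfg <- psa_config(n_iterations = 8, seed = 2, cost_sd_frac = 0)
  p <- run_psa(b, cfg)
  det <- run_analysis(b)$economics$summary
  merged <- merge(p$summary, det, by.x = c("horizon", "measure"),
                  by.y = c("horizon", "measure"))
  ok <- is.finite(merged$point)
  expect_identical(merged$point[ok], merged$lower[ok])
  expect_identical(merged$point[ok], merged$upper[ok])
  expect_identical(merged$point[ok], merged$value[ok])
})

test_that("a policy with no effect is never cost saving under PSA", {
  p <- run_psa(fixture_null_bundle(), psa_config(n_iterations = 30, seed = 9))
  expect_true(all(p$probabilities$p_cost_saving == 0))
  expect_equal(p$n_failures, 0L)
})

test_that("with only cost variation the health outcomes have zero UI width", {
  b <- fixture_bundle()
  cfg <- psa_config(n_iterations = 10, seed = 4, vary_intake = FALSE,
                    vary_rr = FALSE)
  p <- run_psa(b, cfg)
  s <- p$summary
  for (m in c("events_averted", "deaths_averted", "halys_gained")) {
    sm <- s[s$measure == m, ]
    expect_equal(sm$lower, sm$upper)
  }
  # costs still vary
  net <- s[s$measure == "net_cost" & s$horizon == "10y", ]
  expect_lt(net$lower, net$upper)
})

test_that("PSA medians converge as iterations grow", {
  b <- fixture_bundle()
  p1 <- run_psa(b, psa_config(n_iterations = 300, seed = 21),
                horizons = 10)
  p2 <- run_psa(b, psa_config(n_iterations = 900, seed = 22),
                horizons = 10)
  x <- p1$draws[, "10y.halys_gained"]
  # bootstrap standard error of the smaller sample's median
  set.seed(33)
  bs <- replicate(200, nearest_rank_percentile(sample(x, replace = TRUE), 0.5))
  se <- sd(bs)
  m1 <- p1$summary$point[p1$summary$measure == "halys_gained"]
  m2 <- p2$summary$point[p2$summary$measure == "halys_gained"]
  expect_lt(abs(m1 - m2), 5 * se)
})

test_that("sensitivity scenarios move outcomes in the expected directions", {
  b <- fixture_bundle()
  sens <- run_sensitivity_suite(b, c("primary", "discount_0", "discount_6",
                                     "residual_tfa_0.1", "no_industry_costs",
                                     "products_x2", "monitoring_plus50"))
  v <- function(sc, h, m) {
    sens$value[sens$scenario == sc & sens$horizon == h & sens$measure == m]
  }
  # industry costs are costs-only: net cost falls, HALYs unchanged
  expect_lt(v("no_industry_costs", "10y", "net_cost"),
            v("primary", "10y", "net_cost"))
  expect_equal(v("no_industry_costs", "10y", "halys_gained"),
               v("primary", "10y", "halys_gained"))
  # discounting: lifetime HALYs shrink as the rate rises
  expect_gt(v("discount_0", "lifetime", "halys_gained"),
            v("primary", "lifetime", "halys_gained"))
  expect_gt(v("primary", "lifetime", "halys_gained"),
            v("discount_6", "lifetime", "halys_gained"))
  # residual TFA intake after the intervention reduces the gains
  expect_lt(v("residual_tfa_0.1", "lifetime", "halys_gained"),
            v("primary", "lifetime", "halys_gained"))
  expect_gt(v("residual_tfa_0.1", "lifetime", "halys_gained"), 0)
  # doubled products and higher monitoring raise implementation costs only
  expect_gt(v("products_x2", "10y", "industry_cost"),
            v("primary", "10y", "industry_cost"))
  expect_gt(v("monitoring_plus50", "10y", "government_cost"),
            v("primary", "10y", "government_cost"))
})

test_that("unknown sensitivity scenarios fail with the valid names listed", {
  expect_error(run_sensitivity_suite(fixture_bundle(), "not_a_scenario"),
               "unknown scenario.*discount_0")
})
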