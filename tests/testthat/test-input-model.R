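test_that("lognormal moment matching recovers mean and SD analytically", {
  cases <- list(c(0.25, 0.125), c(2, 1), c(0.31, 0.155), c(5, 0.5))
  for (cs in cases) {
    p <- lognormal_params(cs[1], cs[2])
    mean_rec <- exp(p$meanlog + p$sdlog^2 / 2)
    sd_rec <- mean_rec * sqrt(exp(p$sdlog^2) - 1)
    expect_equal(mean_rec, cs[1], tolerance = 1e-12)
    expect_equal(sd_rec, cs[2], tolerance = 1e-12)
  }
  # closed form for the (0.25, 0.125) case
  p <- lognormal_params(0.25, 0.125)
  expect_equal(p$sdlog, sqrt(log(1 + (0.125 / 0.25)^2)), tolerance = 1e-15)
  expect_equal(p$meanlog, log(0.25) - p$sdlog^2 / 2, tolerance = 1e-15)
})

test_that("lognormal parameterisation survives a million-draw round trip", {
  p <- lognormal_params(2, 1)
  set.seed(99)
  x <- rlnorm(1e6, p$meanlog, p$sdlog)
  expect_lt(abs(mean(x) - 2), 0.01)
  p <- lognormal_params(0.25, 0.125)
  set.seed(100)
  x <- rlnorm(1e6, p$meanlog, p$sdlog)
  expect_lt(abs(mean(x) - 0.25) / 0.25, 0.005)
  expect_lt(abs(sd(x) - 0.125) / 0.125, 0.005)
})

test_that("degenerate and invalid moment inputs are handled", {
  p <- lognormal_params(1, 0)
  expect_true(p$degenerate)
  expect_identical(p$at, 1)
  expect_error(lognormal_params(0, 0.5), "positive")
  expect_error(lognormal_params(1, -1), "non-negative")
})

test_that("band expansion is piecewise constant for rates, uniform for counts", {
  bands <- age_bands(20, 95)
  v <- seq_along(bands) / 10
  out <- expand_to_single_ages(bands, v, kind = "rate")
  expect_identical(out$age, 20:100)
  expect_equal(out$value[out$age %in% 20:24], rep(0.1, 5))
  expect_equal(out$value[out$age == 100], v[length(v)])
  # monotone band values stay monotone after expansion
  expect_true(all(diff(out$value) >= 0))
  # counts: band totals preserved
  cnt <- expand_to_single_ages(bands, rep(1000, length(bands)), kind = "count")
  expect_equal(cnt$value[cnt$age %in% 20:24], rep(200, 5))
  expect_equal(sum(cnt$value), 1000 * length(bands))
  expect_equal(cnt$value[cnt$age == 100], 0)
})

test_that("a gap in the band tiling is rejected", {
  bands <- age_bands(20, 95)[-3]
  expect_error(expand_to_single_ages(bands, seq_along(bands), kind = "rate"),
               "gap in age bands")
})

test_that("bundle writes and reloads bit-exactly with 30 exposure strata", {
  b <- fixture_bundle()
  dir <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  # the CSV boundary is band-resolution: one write/load lands the bundle
  # there, after which the round trip must be bit-exact
  write_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_equal(nrow(b2$exposure), 30L)
  # band means and band population totals survive the collapse
  inc5 <- vapply(seq(20, 95, 5), function(a) {
    sel <- b$rates$sex == "female" & b$rates$age >= a & b$rates$age <= a + 4
    mean(b$rates$incidence[sel])
  }, numeric(1))
  expect_equal(b2$rates$incidence[b2$rates$sex == "female" &
                                    b2$rates$age %in% seq(20, 95, 5)],
               inc5, tolerance = 1e-15)
  expect_equal(sum(b2$rates$population), sum(b$rates$population),
               tolerance = 1e-12)
  expect_identical(b2$exposure$mean, b$exposure$mean)
  expect_identical(b2$exposure$sd, b$exposure$sd)
  write_bundle(b2, dir2)
  b3 <- load_bundle(dir2)
  for (col in c("population", "mortality", "incidence", "prevalence",
                "csmr", "yld_ihd", "yld_all", "other_pc")) {
    expect_identical(b3$rates[[col]], b2$rates[[col]])
  }
  expect_identical(b3$exposure$mean, b2$exposure$mean)
  expect_identical(b3$rr$rr, b2$rr$rr)
  expect_identical(b3$rr$log_sd, b2$rr$log_sd)
  expect_identical(b3$costs$gov_schedule$value, b2$costs$gov_schedule$value)
  expect_equal(b3$settings, b2$settings, tolerance = 0)
})

test_that("out-of-range and incomplete inputs are rejected with the stratum named", {
  b <- fixture_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)

  # prevalence above one on a specific row
  f <- file.path(dir, "ihd_prevalence.csv")
  d <- read.csv(f)
  d$value[d$sex == "female" & d$age_group == "40-44"] <- 1.2
  write.csv(d, f, row.names = FALSE)
  expect_error(load_bundle(dir), "prevalence in \\[0, 1\\] violated at female")

  # missing stratum names sex and band
  write_bundle(b, dir)
  d <- read.csv(f)
  d <- d[!(d$sex == "male" & d$age_group == "95-99"), ]
  write.csv(d, f, row.names = FALSE)
  expect_error(load_bundle(dir), "male, 95-99")

  # negative rate names the row
  write_bundle(b, dir)
  d <- read.csv(f)
  d$value[4] <- -0.01
  write.csv(d, f, row.names = FALSE)
  expect_error(load_bundle(dir), "negative value at row 4")
})

test_that("unknown bundle config keys are rejected by name", {
  b <- fixture_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$not_a_real_key <- 1
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  expect_error(load_bundle(dir), "not_a_real_key")
})

test_that("exposure distributions respect their truncation bound", {
  d <- exposure_dist(0.25, 0.125)
  expect_false(d$degenerate)
  expect_equal(d$upper_bound, 0.25 + 10 * 0.125)
  expect_error(exposure_dist(1, 0.5, upper_bound = 0.5), "exceed the mean")
  d0 <- exposure_dist(0, 0)
  expect_true(d0$degenerate)
})
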