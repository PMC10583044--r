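# Input model: age structure, CSV ingestion, validation, band expansion and
# exposure distribution parameterisation.

#' Five-year age band labels
#'
#' @param first,last start of the first and last band.
#' @return character vector of labels such as `"20-24"`.
#' @keywords internal
age_bands <- function(first = 20L, last = 95L) {
  starts <- seq(as.integer(first), as.integer(last), by = 5L)
  sprintf("%d-%d", starts, starts + 4L)
}

# Bands carrying demography and disease inputs (20-24 ... 95-99).
input_bands <- function() age_bands(20L, 95L)

# Bands carrying TFA exposure and relative risks (20-24 ... 90-94, ages 95+
# inherit the last band; 15 bands x 2 sexes = 30 strata).
exposure_bands <- function() age_bands(20L, 90L)

band_start <- function(age_group) as.integer(sub("-.*$", "", age_group))

#' Expand five-year band values to single years of age
#'
#' Rates are carried piecewise-constant into every year of their band; counts
#' are split uniformly (one fifth of the band total per year of age).  Ages
#' beyond the last band inherit its value (rates) or zero (counts), so band
#' inputs ending at 95-99 extend to age 100.
#'
#' @param age_group character band labels (e.g. `"20-24"`), tiling a
#'   contiguous range in five-year steps.
#' @param value numeric band values, same length as `age_group`.
#' @param kind `"rate"` (carried) or `"count"` (split by five).
#' @param ages integer vector of single ages to produce.
#' @return data.frame with columns `age` and `value`.
#' @export
expand_to_single_ages <- function(age_group, value, kind = c("rate", "count"),
                                  ages = AGE_MIN:AGE_MAX) {
  kind <- match.arg(kind)
  if (length(age_group) != length(value)) {
    stop("age_group and value must have equal length", call. = FALSE)
  }
  starts <- band_start(age_group)
  o <- order(starts)
  starts <- starts[o]
  value <- value[o]
  expected <- seq(starts[1], by = 5L, length.out = length(starts))
  if (!identical(as.integer(starts), as.integer(expected))) {
    missing <- setdiff(expected, starts)
    stop(sprintf("gap in age bands: missing band starting at %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  top <- starts[length(starts)] + 4L
  band_of <- findInterval(pmin(ages, top), starts)
  out <- value[band_of]
  if (kind == "count") {
    out <- out / 5
    out[ages > top] <- 0
  }
  data.frame(age = as.integer(ages), value = out)
}

#' Moment-matched lognormal parameters
#'
#' Returns the log-scale parameters of a lognormal distribution whose
#' arithmetic mean and standard deviation equal the inputs.  `sd = 0` marks a
#' degenerate (point-mass) distribution.
#'
#' @param mean,sd arithmetic mean and SD (same units, e.g. %E).
#' @return list with `meanlog`, `sdlog` and logical `degenerate`.
#' @export
lognormal_params <- function(mean, sd) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    return(list(meanlog = NA_real_, sdlog = 0, degenerate = TRUE, at = mean))
  }
  if (mean <= 0) stop("mean must be positive when sd > 0", call. = FALSE)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog, degenerate = FALSE, at = NA_real_)
}

#' Construct a TFA intake distribution
#'
#' Lognormal intake distribution (moment matched), truncated at
#' `upper_bound` with renormalisation.  A zero SD gives a point mass.
#'
#' @param mean,sd arithmetic mean and SD of intake (%E).
#' @param upper_bound integration limit m (%E); defaults to
#'   `mean + sd_mult * sd`.
#' @param sd_mult multiplier used for the default upper bound.
#' @return object of class `exposure_dist`.
#' @export
exposure_dist <- function(mean, sd, upper_bound = NULL, sd_mult = 10) {
  if (mean < 0 || sd < 0) stop("mean and sd must be non-negative", call. = FALSE)
  degenerate <- sd == 0
  if (is.null(upper_bound)) {
    upper_bound <- if (degenerate) mean + 1 else mean + sd_mult * sd
  }
  if (!degenerate && upper_bound <= mean) {
    stop("upper_bound must exceed the mean", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, upper_bound = upper_bound,
                 degenerate = degenerate),
            class = "exposure_dist")
}

# ---------------------------------------------------------------------------
# CSV ingestion

bundle_files <- function() {
  c(population = "population.csv",
    mortality = "all_cause_mortality.csv",
    incidence = "ihd_incidence.csv",
    prevalence = "ihd_prevalence.csv",
    csmr = "ihd_csmr.csv",
    yld_ihd = "ihd_yld_rate.csv",
    yld_all = "all_cause_yld_rate.csv",
    other_pc = "other_healthcare_cost.csv",
    the = "total_health_expenditure.csv",
    intake = "tfa_intake.csv",
    rr = "rr_ihd.csv",
    gov = "gov_cost_schedule.csv")
}

read_stratified <- function(path, bands, value_cols = "value",
                            allow_negative = FALSE) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_group", value_cols)
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", basename(path),
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  for (s in SEXES) for (b in bands) {
    if (!any(d$sex == s & d$age_group == b)) {
      stop(sprintf("%s: missing stratum: %s, %s", basename(path), s, b),
           call. = FALSE)
    }
  }
  extra <- setdiff(unique(d$age_group), bands)
  if (length(extra)) {
    stop(sprintf("%s: unexpected age_group: %s", basename(path),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (vc in value_cols) {
    d[[vc]] <- as.numeric(d[[vc]])
    bad <- which(!is.finite(d[[vc]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric %s at row %d", basename(path), vc, bad[1]),
           call. = FALSE)
    }
    if (!allow_negative) {
      bad <- which(d[[vc]] < 0)
      if (length(bad)) {
        stop(sprintf("%s: negative %s at row %d (%s, %s)", basename(path), vc,
                     bad[1], d$sex[bad[1]], d$age_group[bad[1]]), call. = FALSE)
      }
    }
  }
  d[order(d$sex, band_start(d$age_group)), , drop = FALSE]
}

# Keys accepted in a bundle config file.
bundle_config_keys <- function() {
  c("discount_rate", "base_year", "exchange_rate",
    "threshold_very_cost_effective", "threshold_cost_effective",
    "tmrel", "upper_bound_sd_mult", "discount_halys",
    "acute_event_cost_male", "acute_event_cost_female",
    "prevalent_case_cost", "component_event_costs",
    "event_mix_male", "event_mix_female",
    "reformulation_cost_per_product", "n_products",
    "annual_industry_fraction", "industry_cost_multiplier",
    "gov_recurrent_categories",
    "intervention_intake_mean", "intervention_intake_sd")
}

default_settings <- function() {
  list(discount_rate = 0.03,
       base_year = 2019L,
       exchange_rate = 103,
       thresholds = c(very_cost_effective = 1720, cost_effective = 5161),
       tmrel = 0,
       upper_bound_sd_mult = 10,
       discount_halys = TRUE)
}

#' Load a full model input bundle from CSV files plus a config file
#'
#' Reads the per-table CSV file set (columns `sex`, `age_group`, `value`
#' and, for intake, `sd`), the government cost schedule, the relative risk
#' table and a YAML config of economic settings and scalar cost inputs, and
#' returns a validated bundle.
#'
#' @param input_dir directory holding the CSV file set.
#' @param config_path YAML config; defaults to `config.yaml` in `input_dir`.
#' @return object of class `tfa_bundle`.
#' @seealso [write_bundle()], [validate_bundle()], [generate_bundle()]
#' @export
load_bundle <- function(input_dir,
                        config_path = file.path(input_dir, "config.yaml")) {
  files <- bundle_files()
  p <- function(key) file.path(input_dir, files[[key]])

  cfg <- if (file.exists(config_path)) yaml::read_yaml(config_path) else list()
  unknown <- setdiff(names(cfg), bundle_config_keys())
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  st <- default_settings()
  for (k in c("discount_rate", "base_year", "exchange_rate", "tmrel",
              "upper_bound_sd_mult", "discount_halys")) {
    if (!is.null(cfg[[k]])) st[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$threshold_very_cost_effective)) {
    st$thresholds["very_cost_effective"] <- cfg$threshold_very_cost_effective
  }
  if (!is.null(cfg$threshold_cost_effective)) {
    st$thresholds["cost_effective"] <- cfg$threshold_cost_effective
  }

  ib <- input_bands()
  eb <- exposure_bands()

  tables <- list(
    population = read_stratified(p("population"), ib),
    mortality = read_stratified(p("mortality"), ib),
    incidence = read_stratified(p("incidence"), ib),
    prevalence = read_stratified(p("prevalence"), ib),
    csmr = read_stratified(p("csmr"), ib),
    yld_ihd = read_stratified(p("yld_ihd"), ib),
    yld_all = read_stratified(p("yld_all"), ib),
    other_pc = read_stratified(p("other_pc"), ib),
    the = read_stratified(p("the"), ib)
  )

  rates <- do.call(rbind, lapply(SEXES, function(s) {
    one <- function(key, kind = "rate") {
      d <- tables[[key]]
      d <- d[d$sex == s, ]
      expand_to_single_ages(d$age_group, d$value, kind = kind)$value
    }
    data.frame(sex = s, age = AGE_MIN:AGE_MAX,
               population = one("population", "count"),
               mortality = one("mortality"),
               incidence = one("incidence"),
               prevalence = one("prevalence"),
               csmr = one("csmr"),
               yld_ihd = one("yld_ihd"),
               yld_all = one("yld_all"),
               other_pc = one("other_pc"),
               total_expenditure = one("the"),
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL

  intake <- read_stratified(p("intake"), eb, value_cols = c("value", "sd"))
  exposure <- data.frame(sex = intake$sex, age_group = intake$age_group,
                         mean = intake$value, sd = intake$sd,
                         int_mean = cfg$intervention_intake_mean %||% 0,
                         int_sd = cfg$intervention_intake_sd %||% 0,
                         stringsAsFactors = FALSE)

  rrd <- read.csv(p("rr"), stringsAsFactors = FALSE)
  if (!all(c("age_group", "value", "ci_low", "ci_high") %in% names(rrd))) {
    stop("rr_ihd.csv: expected columns age_group, value, ci_low, ci_high",
         call. = FALSE)
  }
  miss <- setdiff(eb, rrd$age_group)
  if (length(miss)) {
    stop(sprintf("rr_ihd.csv: missing age_group: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  rrd <- rrd[order(band_start(rrd$age_group)), ]
  rr <- data.frame(age_group = rrd$age_group, rr = rrd$value,
                   log_sd = (log(rrd$ci_high) - log(rrd$ci_low)) /
                     (2 * qnorm(0.975)),
                   stringsAsFactors = FALSE)

  govd <- read.csv(p("gov"), stringsAsFactors = FALSE)
  if (!all(c("category", "year", "value") %in% names(govd))) {
    stop("gov_cost_schedule.csv: expected columns category, year, value",
         call. = FALSE)
  }
  govd$value <- as.numeric(govd$value)
  govd$year <- as.integer(govd$year)
  gov_schedule <- govd[order(govd$category, govd$year), ]
  rownames(gov_schedule) <- NULL

  num <- function(key, default) as.numeric(cfg[[key]] %||% default)
  costs <- list(
    acute_event_cost = c(female = num("acute_event_cost_female", 6083),
                         male = num("acute_event_cost_male", 6283)),
    prevalent_case_cost = num("prevalent_case_cost", 336),
    component_event_costs = unlist(cfg$component_event_costs %||%
      list(mi = 1996, angina = 1237, arrest = 1026)),
    event_mix = list(
      female = unlist(cfg$event_mix_female %||%
        list(mi = 0.20, angina = 0.70, arrest = 0.10)),
      male = unlist(cfg$event_mix_male %||%
        list(mi = 0.35, angina = 0.55, arrest = 0.10))),
    gov_schedule = gov_schedule,
    gov_recurrent = cfg$gov_recurrent_categories %||%
      c("human_resources", "administration"),
    reformulation_cost_per_product = num("reformulation_cost_per_product", 25000),
    n_products = num("n_products", 99),
    annual_industry_fraction = num("annual_industry_fraction", 0.01),
    industry_cost_multiplier = num("industry_cost_multiplier", 1.79)
  )

  bundle <- structure(list(rates = rates, exposure = exposure, rr = rr,
                           costs = costs, settings = st),
                      class = "tfa_bundle")
  validate_bundle(bundle)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model input bundle
#'
#' Checks stratum completeness (both sexes, ages 20-100), range constraints
#' (prevalence in \[0,1\], non-negative rates and costs, cause-specific
#' mortality not exceeding all-cause mortality, IHD YLD rate not exceeding
#' the all-cause YLD rate), event-mix normalisation and threshold ordering.
#' Errors name the offending stratum.
#'
#' @param bundle a `tfa_bundle`.
#' @return invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_bundle <- function(bundle) {
  r <- bundle$rates
  fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
  for (s in SEXES) {
    got <- sort(r$age[r$sex == s])
    if (!identical(as.integer(got), AGE_MIN:AGE_MAX)) {
      fail("rates: incomplete ages for sex %s", s)
    }
  }
  chk <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad)) {
      fail("%s violated at %s, age %d", what, r$sex[bad[1]], r$age[bad[1]])
    }
  }
  chk(r$population >= 0, "population >= 0")
  chk(r$mortality >= 0 & r$mortality <= 1.5, "mortality in [0, 1.5]")
  chk(r$incidence >= 0, "incidence >= 0")
  chk(r$prevalence >= 0 & r$prevalence <= 1, "prevalence in [0, 1]")
  chk(r$csmr >= 0, "csmr >= 0")
  chk(r$csmr <= r$mortality + 1e-12, "csmr <= all-cause mortality")
  chk(r$yld_ihd >= 0, "IHD YLD rate >= 0")
  chk(r$yld_ihd <= r$yld_all + 1e-12, "IHD YLD rate <= all-cause YLD rate")
  chk(r$other_pc >= 0, "healthcare expenditure >= 0")

  e <- bundle$exposure
  for (s in SEXES) {
    got <- e$age_group[e$sex == s]
    miss <- setdiff(exposure_bands(), got)
    if (length(miss)) fail("exposure: missing stratum: %s, %s", s, miss[1])
  }
  if (any(e$mean < 0) || any(e$sd < 0)) fail("exposure mean/sd must be >= 0")
  if (any(e$int_mean < 0) || any(e$int_sd < 0)) {
    fail("intervention intake mean/sd must be >= 0")
  }

  rr <- bundle$rr
  miss <- setdiff(exposure_bands(), rr$age_group)
  if (length(miss)) fail("rr: missing age_group %s", miss[1])
  if (any(rr$rr <= 0)) fail("relative risks must be positive")
  if (any(rr$log_sd < 0)) fail("rr log-sd must be >= 0")

  co <- bundle$costs
  for (s in SEXES) {
    if (abs(sum(co$event_mix[[s]]) - 1) > 1e-9) {
      fail("event mix for %s must sum to 1", s)
    }
  }
  flat <- c(co$acute_event_cost, co$prevalent_case_cost,
            co$component_event_costs, co$reformulation_cost_per_product,
            co$n_products, co$gov_schedule$value)
  if (any(flat < 0)) fail("costs must be non-negative")
  if (co$annual_industry_fraction < 0 || co$annual_industry_fraction > 1) {
    fail("annual_industry_fraction must lie in [0, 1]")
  }
  gcat <- unique(co$gov_schedule$category)
  if (length(gcat) < 1) fail("government cost schedule is empty")
  miss <- setdiff(co$gov_recurrent, gcat)
  if (length(miss)) {
    fail("gov schedule missing recurrent category: %s", miss[1])
  }

  st <- bundle$settings
  if (st$discount_rate < 0 || st$discount_rate > 0.2) {
    fail("discount_rate must lie in [0, 0.2]")
  }
  th <- st$thresholds
  if (any(th <= 0) || th[1] >= th[2]) {
    fail("WHO thresholds must be positive and ordered")
  }
  invisible(TRUE)
}

#' Write a bundle back to its CSV file set
#'
#' Inverse of [load_bundle()]: emits the per-table CSVs (full `%.17g`
#' precision so a reload reproduces all values bit-exactly) and a
#' `config.yaml` holding the settings and scalar cost inputs.
#'
#' @param bundle a `tfa_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- bundle_files()
  r <- bundle$rates
  ib <- input_bands()

  fmt <- function(x) sprintf("%.17g", x)
  write_table <- function(d, file) {
    for (nm in names(d)) if (is.numeric(d[[nm]])) d[[nm]] <- fmt(d[[nm]])
    write.csv(d, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }

  # Collapse single ages back to bands: rates take the band mean (the
  # identity for band-constant data), counts take the band sum.
  collapse <- function(col, kind = "rate") {
    do.call(rbind, lapply(SEXES, function(s) {
      rs <- r[r$sex == s, ]
      starts <- band_start(ib)
      v <- vapply(starts, function(a) {
        sel <- rs$age >= a & rs$age <= a + 4
        if (kind == "count") sum(rs[[col]][sel]) else mean(rs[[col]][sel])
      }, numeric(1))
      data.frame(sex = s, age_group = ib, value = v, stringsAsFactors = FALSE)
    }))
  }
  write_table(collapse("population", "count"), files[["population"]])
  write_table(collapse("mortality"), files[["mortality"]])
  write_table(collapse("incidence"), files[["incidence"]])
  write_table(collapse("prevalence"), files[["prevalence"]])
  write_table(collapse("csmr"), files[["csmr"]])
  write_table(collapse("yld_ihd"), files[["yld_ihd"]])
  write_table(collapse("yld_all"), files[["yld_all"]])
  write_table(collapse("other_pc"), files[["other_pc"]])
  write_table(collapse("total_expenditure"), files[["the"]])

  e <- bundle$exposure
  write_table(data.frame(sex = e$sex, age_group = e$age_group,
                         value = e$mean, sd = e$sd),
              files[["intake"]])

  rr <- bundle$rr
  z <- qnorm(0.975)
  write_table(data.frame(age_group = rr$age_group, value = rr$rr,
                         ci_low = exp(log(rr$rr) - z * rr$log_sd),
                         ci_high = exp(log(rr$rr) + z * rr$log_sd)),
              files[["rr"]])

  write_table(bundle$costs$gov_schedule, files[["gov"]])

  co <- bundle$costs
  st <- bundle$settings
  cfg <- list(
    discount_rate = st$discount_rate,
    base_year = st$base_year,
    exchange_rate = st$exchange_rate,
    threshold_very_cost_effective = unname(st$thresholds[1]),
    threshold_cost_effective = unname(st$thresholds[2]),
    tmrel = st$tmrel,
    upper_bound_sd_mult = st$upper_bound_sd_mult,
    discount_halys = st$discount_halys,
    acute_event_cost_female = unname(co$acute_event_cost[["female"]]),
    acute_event_cost_male = unname(co$acute_event_cost[["male"]]),
    prevalent_case_cost = co$prevalent_case_cost,
    component_event_costs = as.list(co$component_event_costs),
    event_mix_female = as.list(co$event_mix$female),
    event_mix_male = as.list(co$event_mix$male),
    reformulation_cost_per_product = co$reformulation_cost_per_product,
    n_products = co$n_products,
    annual_industry_fraction = co$annual_industry_fraction,
    industry_cost_multiplier = co$industry_cost_multiplier,
    gov_recurrent_categories = co$gov_recurrent,
    intervention_intake_mean = unique(bundle$exposure$int_mean)[1],
    intervention_intake_sd = unique(bundle$exposure$int_sd)[1]
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 17)
  invisible(dir)
}
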