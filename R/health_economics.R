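# Health economics: healthcare cost streams driven by the life table
# differences, government and industry implementation cost streams,
# discounting, net cost, ICER, ROI and WHO threshold classification.
# Sign convention: cost streams are intervention-minus-reference changes,
# so healthcare savings are negative amounts.

#' Pooled acute IHD event cost
#'
#' Weights the component event costs (myocardial infarction, angina,
#' cardiac arrest) by their share of acute IHD presentations for a sex.
#'
#' @param component_costs named numeric: cost per event for each component.
#' @param event_mix named numeric proportions (same names), summing to 1;
#'   or a list keyed by sex, in which case `sex` selects the element.
#' @param sex optional sex key into an `event_mix` list.
#' @return pooled cost per acute event.
#' @export
pooled_incident_cost <- function(component_costs, event_mix, sex = NULL) {
  if (!is.null(sex)) event_mix <- event_mix[[sex]]
  if (abs(sum(event_mix) - 1) > 1e-9) {
    stop("event mix must sum to 1", call. = FALSE)
  }
  nm <- names(event_mix)
  if (!all(nm %in% names(component_costs))) {
    stop("event mix and component costs must share names", call. = FALSE)
  }
  sum(component_costs[nm] * event_mix)
}

#' Discount a yearly amount stream
#'
#' Year 1 is the policy-start year and is undiscounted; year t is
#' multiplied by `(1 + rate)^-(t - 1)`.
#'
#' @param stream numeric amounts for years 1, 2, ...
#' @param rate annual discount rate, >= 0.
#' @return discounted stream, same length.
#' @export
discount <- function(stream, rate) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  stream * (1 + rate)^(-(seq_along(stream) - 1))
}

#' Healthcare cost change stream
#'
#' Per calendar year: change in acute (incident) IHD costs, prevalent-case
#' costs and healthcare costs of all other conditions in added years of
#' life.  The last term charges the per-capita non-IHD expenditure to the
#' change in life years at each age, which is why total savings are
#' smaller in magnitude than the IHD-specific savings.
#'
#' @param run a `pmslt_run`.
#' @param costs the bundle's cost inputs.
#' @return data.frame (year, ihd_incident, ihd_prevalent, ihd_total,
#'   other, total), undiscounted US$ per year.
#' @export
healthcare_cost_stream <- function(run, costs) {
  Tmax <- run$n_cycles
  inc <- prev <- oth <- numeric(Tmax)
  for (s in SEXES) {
    ref <- run$by_sex[[s]]$reference
    intv <- run$by_sex[[s]]$intervention
    rt <- run$by_sex[[s]]$rates
    d_events <- rowSums(intv$events - ref$events)
    d_prevpy <- rowSums(intv$prev_py - ref$prev_py)
    inc <- inc + d_events * costs$acute_event_cost[[s]]
    prev <- prev + d_prevpy * costs$prevalent_case_cost
    # other-condition costs follow the change in life years at each age
    oc <- matrix(0, Tmax, length(ref$entry_ages))
    has <- !is.na(ref$age)
    oc[has] <- rt$other_pc[ref$age[has] - AGE_MIN + 1L]
    oth <- oth + rowSums((intv$ly - ref$ly) * oc)
  }
  data.frame(year = seq_len(Tmax), ihd_incident = inc, ihd_prevalent = prev,
             ihd_total = inc + prev, other = oth, total = inc + prev + oth)
}

#' Government implementation cost stream
#'
#' The five-category schedule covers years 1-5; beyond year 5 only the
#' recurrent categories (by default human resources and administration)
#' carry forward at their year-5 level.
#'
#' @param schedule data.frame (category, year, value) covering years 1-5.
#' @param horizon number of years to produce.
#' @param recurrent categories continuing after year 5.
#' @param uplift named numeric multipliers per category (e.g.
#'   `c(human_resources = 1.5)` for 50% greater monitoring costs).
#' @return data.frame (year, cost), undiscounted.
#' @export
government_cost_stream <- function(schedule, horizon,
                                   recurrent = c("human_resources",
                                                 "administration"),
                                   uplift = NULL) {
  cats <- unique(schedule$category)
  miss <- setdiff(recurrent, cats)
  if (length(miss)) {
    stop(sprintf("schedule missing category: %s", miss[1]), call. = FALSE)
  }
  val <- function(cat, yr) {
    v <- schedule$value[schedule$category == cat & schedule$year == yr]
    if (length(v) == 0) 0 else sum(v)
  }
  mult <- function(cat) {
    if (!is.null(uplift) && cat %in% names(uplift)) uplift[[cat]] else 1
  }
  cost <- numeric(horizon)
  for (t in seq_len(horizon)) {
    for (cat in cats) {
      v <- if (t <= 5) val(cat, t) else if (cat %in% recurrent) val(cat, 5) else 0
      cost[t] <- cost[t] + v * mult(cat)
    }
  }
  data.frame(year = seq_len(horizon), cost = cost)
}

#' Industry reformulation cost stream
#'
#' Year 1 carries the reformulation lump sum (per-product cost times the
#' number of products, scaled by the configured currency
#' conversion/inflation multiplier); every later year costs
#' `annual_fraction` of the lump.
#'
#' @param cost_per_product source-currency cost per reformulated product.
#' @param n_products number of products containing iTFA.
#' @param annual_fraction ongoing annual cost as a fraction of the lump.
#' @param horizon number of years.
#' @param multiplier currency conversion and inflation multiplier applied
#'   to the lump (1 keeps the source currency).
#' @return data.frame (year, cost), undiscounted.
#' @export
industry_cost_stream <- function(cost_per_product, n_products,
                                 annual_fraction, horizon, multiplier = 1) {
  stopifnot(cost_per_product >= 0, n_products >= 0, annual_fraction >= 0)
  lump <- cost_per_product * n_products * multiplier
  cost <- c(lump, rep(annual_fraction * lump, max(horizon - 1, 0)))
  data.frame(year = seq_len(horizon), cost = cost[seq_len(horizon)])
}

#' Cost-effectiveness summary of one horizon
#'
#' ICER is net cost over HALYs gained; a negative net cost with positive
#' HALYs is cost saving (dominant).  ROI is healthcare savings returned
#' per unit of government spend.  The implementation-only ICER excludes
#' healthcare savings.  Classification against the WHO thresholds is
#' half-open (`< threshold`).
#'
#' @param net_cost net cost (healthcare change + implementation), US$.
#' @param halys HALYs gained.
#' @param gov_cost,healthcare_savings for the ROI (savings as a positive
#'   number); `NA` to skip.
#' @param implementation_cost government + industry cost; `NA` to skip the
#'   implementation-only ICER.
#' @param thresholds length-2 vector: very cost-effective, cost-effective
#'   (US$/HALY).
#' @return object of class `ce_result`: list with `net_cost`, `halys`,
#'   `icer`, `icer_implementation_only`, `roi`, `cost_saving`,
#'   `classification` (one of cost-saving, very cost-effective,
#'   cost-effective, not cost-effective, undefined).
#' @export
cost_effectiveness <- function(net_cost, halys, gov_cost = NA,
                               healthcare_savings = NA,
                               implementation_cost = NA,
                               thresholds = c(very_cost_effective = 1720,
                                              cost_effective = 5161)) {
  if (any(thresholds <= 0) || thresholds[1] >= thresholds[2]) {
    stop("thresholds must be positive and ordered", call. = FALSE)
  }
  icer <- if (halys > 0) net_cost / halys else NA_real_
  icer_impl <- if (!is.na(implementation_cost) && halys > 0) {
    implementation_cost / halys
  } else NA_real_
  roi <- if (!is.na(gov_cost) && !is.na(healthcare_savings) && gov_cost > 0) {
    healthcare_savings / gov_cost
  } else NA_real_
  cost_saving <- net_cost < 0
  classification <- if (halys <= 0) {
    if (cost_saving) "cost-saving" else "undefined"
  } else if (cost_saving) {
    "cost-saving"
  } else if (icer < thresholds[1]) {
    "very cost-effective"
  } else if (icer < thresholds[2]) {
    "cost-effective"
  } else {
    "not cost-effective"
  }
  structure(list(net_cost = net_cost, halys = halys, icer = icer,
                 icer_implementation_only = icer_impl, roi = roi,
                 cost_saving = cost_saving, classification = classification),
            class = "ce_result")
}

#' Share of packaged products containing iTFA
#'
#' @param n_itfa products with ingredients indicative of iTFA.
#' @param n_total unique packaged products assessed.
#' @return percentage.
#' @export
itfa_product_share <- function(n_itfa, n_total) {
  stopifnot(n_total > 0, n_itfa >= 0)
  100 * n_itfa / n_total
}

#' Assemble cost streams and cost-effectiveness per horizon
#'
#' Builds the healthcare, government and industry cost streams for a run,
#' discounts them at the settings rate and accumulates them over each
#' horizon together with the health outcome differences.
#'
#' @param run a `pmslt_run`.
#' @param bundle the `tfa_bundle` the run was produced from.
#' @param horizons numeric years; `Inf` for lifetime.
#' @return list with `streams` (per-year undiscounted and discounted
#'   component costs), `summary` (tidy horizon x measure data.frame, US$),
#'   and `ce` (per-horizon [cost_effectiveness()] results).
#' @export
economics_summary <- function(run, bundle, horizons = c(5, 10, Inf)) {
  st <- bundle$settings
  co <- bundle$costs
  Tmax <- run$n_cycles
  rate <- st$discount_rate

  hc <- healthcare_cost_stream(run, co)
  gov <- government_cost_stream(co$gov_schedule, Tmax,
                                recurrent = co$gov_recurrent)
  ind <- industry_cost_stream(co$reformulation_cost_per_product,
                              co$n_products, co$annual_industry_fraction,
                              Tmax, multiplier = co$industry_cost_multiplier)
  streams <- data.frame(
    year = seq_len(Tmax),
    ihd_healthcare = hc$ihd_total, other_healthcare = hc$other,
    total_healthcare = hc$total, government = gov$cost, industry = ind$cost)
  for (nm in c("ihd_healthcare", "other_healthcare", "total_healthcare",
               "government", "industry")) {
    streams[[paste0(nm, "_disc")]] <- discount(streams[[nm]], rate)
  }

  cmp <- compare(run, horizons = horizons, discount_rate = rate,
                 discount_halys = st$discount_halys)
  rows <- list()
  ce <- list()
  for (h in horizons) {
    lab <- horizon_labels(h)
    keep <- seq_len(min(h, Tmax))
    tot <- function(col) sum(streams[[paste0(col, "_disc")]][keep])
    ihd_hc <- tot("ihd_healthcare")
    hc_all <- tot("total_healthcare")
    gov_h <- tot("government")
    ind_h <- tot("industry")
    impl <- gov_h + ind_h
    net <- hc_all + impl
    tc <- cmp[cmp$horizon == lab & cmp$sex == "total", ]
    ce[[lab]] <- cost_effectiveness(net, tc$halys_gained, gov_cost = gov_h,
                                    healthcare_savings = -hc_all,
                                    implementation_cost = impl,
                                    thresholds = st$thresholds)
    rows[[lab]] <- data.frame(
      horizon = lab,
      measure = c("events_averted", "deaths_averted", "halys_gained",
                  "ly_gained", "pct_events", "pct_ihd_deaths",
                  "ihd_healthcare_cost", "total_healthcare_cost",
                  "government_cost", "industry_cost", "implementation_cost",
                  "net_cost", "icer", "icer_implementation_only", "roi"),
      value = c(tc$events_averted, tc$deaths_averted, tc$halys_gained,
                tc$ly_gained, tc$pct_events, tc$pct_ihd_deaths,
                ihd_hc, hc_all, gov_h, ind_h, impl, net,
                ce[[lab]]$icer, ce[[lab]]$icer_implementation_only,
                ce[[lab]]$roi),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(streams = streams, summary = summary, ce = ce, comparison = cmp)
}
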