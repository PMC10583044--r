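# Probabilistic sensitivity analysis: correlated-free input draws, repeated
# model evaluation, percentile uncertainty intervals and probability
# statements, plus the deterministic univariate sensitivity harness.

#' PSA configuration
#'
#' @param n_iterations Monte Carlo iterations (2000 reproduces the study
#'   conditions).
#' @param seed integer RNG seed; draws are reproducible from
#'   `(seed, iteration)`.
#' @param vary_intake redraw the stratum TFA intake means from their
#'   moment-matched lognormal distributions (SDs kept fixed).
#' @param vary_rr redraw the age-group relative risks lognormally around
#'   their central values.
#' @param vary_healthcare_costs,vary_implementation_costs draw normal
#'   multipliers (mean 1, SD `cost_sd_frac`) for the healthcare cost items
#'   and for each implementation cost category; negative draws are
#'   truncated at 0 and counted.
#' @param cost_sd_frac SD of the cost multipliers as a fraction of the
#'   central estimate.
#' @return object of class `psa_config`.
#' @export
psa_config <- function(n_iterations = 2000L, seed = 1L,
                       vary_intake = TRUE, vary_rr = TRUE,
                       vary_healthcare_costs = TRUE,
                       vary_implementation_costs = TRUE,
                       cost_sd_frac = 0.2) {
  stopifnot(n_iterations >= 1, cost_sd_frac >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 vary_intake = vary_intake, vary_rr = vary_rr,
                 vary_healthcare_costs = vary_healthcare_costs,
                 vary_implementation_costs = vary_implementation_costs,
                 cost_sd_frac = cost_sd_frac),
            class = "psa_config")
}

iteration_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) * 104729 + as.numeric(iteration) * 7919) %%
               2147483647)
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  k <- sum(x < 0)
  x[x < 0] <- 0
  list(x = x, truncated = k)
}

#' Draw a perturbed input bundle for one PSA iteration
#'
#' All draws are independent across parameters and iterations and are
#' reproducible from `(config$seed, iteration)`.
#'
#' @param bundle central `tfa_bundle`.
#' @param config a [psa_config()].
#' @param iteration 1-based iteration index.
#' @return a perturbed `tfa_bundle`; the number of cost draws truncated at
#'   zero is attached as attribute `truncated_draws`.
#' @export
draw_inputs <- function(bundle, config, iteration) {
  set.seed(iteration_seed(config$seed, iteration))
  b <- bundle
  truncated <- 0L

  if (config$vary_intake) {
    e <- b$exposure
    vary <- e$sd > 0 & e$mean > 0
    if (any(vary)) {
      sdlog <- sqrt(log(1 + (e$sd[vary] / e$mean[vary])^2))
      meanlog <- log(e$mean[vary]) - sdlog^2 / 2
      e$mean[vary] <- rlnorm(sum(vary), meanlog, sdlog)
    }
    vary_i <- e$int_sd > 0 & e$int_mean > 0
    if (any(vary_i)) {
      sdlog <- sqrt(log(1 + (e$int_sd[vary_i] / e$int_mean[vary_i])^2))
      meanlog <- log(e$int_mean[vary_i]) - sdlog^2 / 2
      e$int_mean[vary_i] <- rlnorm(sum(vary_i), meanlog, sdlog)
    }
    b$exposure <- e
  }

  if (config$vary_rr) {
    rr <- b$rr
    sel <- rr$log_sd > 0
    if (any(sel)) {
      b$rr$rr[sel] <- exp(rnorm(sum(sel), log(rr$rr[sel]), rr$log_sd[sel]))
    }
  }

  frac <- config$cost_sd_frac
  if (config$vary_healthcare_costs && frac > 0) {
    d <- rnorm_trunc0(4, 1, frac)
    truncated <- truncated + d$truncated
    b$costs$acute_event_cost["female"] <-
      b$costs$acute_event_cost[["female"]] * d$x[1]
    b$costs$acute_event_cost["male"] <-
      b$costs$acute_event_cost[["male"]] * d$x[2]
    b$costs$prevalent_case_cost <- b$costs$prevalent_case_cost * d$x[3]
    b$rates$other_pc <- b$rates$other_pc * d$x[4]
  }

  if (config$vary_implementation_costs && frac > 0) {
    sched <- b$costs$gov_schedule
    cats <- unique(sched$category)
    d <- rnorm_trunc0(length(cats) + 2, 1, frac)
    truncated <- truncated + d$truncated
    for (k in seq_along(cats)) {
      sel <- sched$category == cats[k]
      sched$value[sel] <- sched$value[sel] * d$x[k]
    }
    b$costs$gov_schedule <- sched
    b$costs$reformulation_cost_per_product <-
      b$costs$reformulation_cost_per_product * d$x[length(cats) + 1]
    b$costs$annual_industry_fraction <-
      min(b$costs$annual_industry_fraction * d$x[length(cats) + 2], 1)
  }

  attr(b, "truncated_draws") <- truncated
  b
}

#' Nearest-rank percentile
#'
#' Percentile of a sample by the nearest-rank rule on the sorted draws
#' (rank `ceiling(p * n)`); ties are broken by the lower index of the
#' stable sort.
#'
#' @param x numeric sample.
#' @param p probability in (0, 1\].
#' @return the sample percentile.
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x, method = "radix")[max(1L, ceiling(p * length(x)))]
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the full pipeline (PIF, life table, economics) once per draw and
#' summarises every horizon x outcome as the 50th (point) and 2.5th/97.5th
#' (95% UI) nearest-rank percentiles, with probabilities of cost saving
#' and of falling under each WHO threshold (net and implementation-only
#' ICERs).
#'
#' @param bundle central `tfa_bundle`.
#' @param config a [psa_config()].
#' @param horizons numeric years; `Inf` for lifetime.
#' @return object of class `psa_summary`: list with `summary` (horizon,
#'   measure, point, lower, upper), `probabilities`, `n_iterations`,
#'   `n_failures`, `truncated_draws`, and the raw `draws` matrix.
#' @export
run_psa <- function(bundle, config = psa_config(), horizons = c(5, 10, Inf)) {
  cf <- derive_case_fatality(bundle)
  n <- config$n_iterations
  draws <- NULL
  failures <- 0L
  truncated <- 0L
  for (it in seq_len(n)) {
    res <- tryCatch({
      bi <- draw_inputs(bundle, config, it)
      truncated <- truncated + attr(bi, "truncated_draws")
      out <- run_analysis(bi, cf = cf, horizons = horizons)
      s <- out$economics$summary
      setNames(s$value, paste(s$horizon, s$measure, sep = "."))
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > max(1, 0.01 * n)) {
        stop(sprintf("PSA aborted: %d of %d iterations failed", failures, it),
             call. = FALSE)
      }
      next
    }
    if (is.null(draws)) {
      draws <- matrix(NA_real_, n, length(res),
                      dimnames = list(NULL, names(res)))
    }
    draws[it, ] <- res
  }
  draws <- draws[rowSums(is.na(draws)) < ncol(draws), , drop = FALSE]

  labs <- horizon_labels(horizons)
  key <- do.call(rbind, strsplit(colnames(draws), ".", fixed = TRUE))
  summ <- data.frame(horizon = key[, 1], measure = key[, 2],
                     point = NA_real_, lower = NA_real_, upper = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(ncol(draws))) {
    x <- draws[, k]
    x <- x[is.finite(x)]
    if (!length(x)) next
    summ$point[k] <- nearest_rank_percentile(x, 0.5)
    summ$lower[k] <- nearest_rank_percentile(x, 0.025)
    summ$upper[k] <- nearest_rank_percentile(x, 0.975)
  }

  th <- bundle$settings$thresholds
  probs <- do.call(rbind, lapply(labs, function(lab) {
    net <- draws[, paste0(lab, ".net_cost")]
    halys <- draws[, paste0(lab, ".halys_gained")]
    icer <- ifelse(halys > 0, net / halys, Inf)
    icer[net < 0 & halys > 0] <- -Inf
    impl <- draws[, paste0(lab, ".implementation_cost")]
    icer_impl <- ifelse(halys > 0, impl / halys, Inf)
    data.frame(horizon = lab,
               p_cost_saving = mean(net < 0),
               p_very_cost_effective = mean(icer < th[1]),
               p_cost_effective = mean(icer < th[2]),
               p_impl_only_very_cost_effective = mean(icer_impl < th[1]),
               p_impl_only_cost_effective = mean(icer_impl < th[2]),
               stringsAsFactors = FALSE)
  }))

  structure(list(summary = summ, probabilities = probs,
                 n_iterations = nrow(draws), n_failures = failures,
                 truncated_draws = truncated, draws = draws),
            class = "psa_summary")
}

# ---------------------------------------------------------------------------
# Univariate sensitivity harness

#' Names of the built-in sensitivity scenarios
#' @return character vector.
#' @export
sensitivity_scenarios <- function() {
  c("primary", "discount_0", "discount_6", "residual_tfa_0.1",
    "intake_minus50", "intake_plus50", "products_x2", "no_industry_costs",
    "monitoring_plus50")
}

apply_scenario <- function(bundle, name) {
  b <- bundle
  switch(name,
    primary = b,
    discount_0 = { b$settings$discount_rate <- 0; b },
    discount_6 = { b$settings$discount_rate <- 0.06; b },
    `residual_tfa_0.1` = {
      b$exposure$int_mean <- 0.10
      b$exposure$int_sd <- 0.01
      b
    },
    intake_minus50 = {
      b$exposure$mean <- b$exposure$mean * 0.5
      b$exposure$sd <- b$exposure$sd * 0.5
      b
    },
    intake_plus50 = {
      b$exposure$mean <- b$exposure$mean * 1.5
      b$exposure$sd <- b$exposure$sd * 1.5
      b
    },
    products_x2 = { b$costs$n_products <- b$costs$n_products * 2; b },
    no_industry_costs = {
      b$costs$reformulation_cost_per_product <- 0
      b
    },
    monitoring_plus50 = {
      sched <- b$costs$gov_schedule
      sel <- sched$category == "human_resources"
      sched$value[sel] <- sched$value[sel] * 1.5
      b$costs$gov_schedule <- sched
      b
    },
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(sensitivity_scenarios(), collapse = ", ")),
         call. = FALSE)
  )
}

#' Deterministic univariate sensitivity suite
#'
#' Runs the deterministic pipeline once per named scenario (discount rates
#' 0%/6%, residual post-intervention intake 0.10 +/- 0.01 %E, pre-intervention
#' intake +/-50%, doubled product count, no industry costs, 50% greater
#' monitoring costs) and returns a tidy table suitable for a
#' cost-effectiveness plane.
#'
#' @param bundle central `tfa_bundle`.
#' @param scenarios scenario names ([sensitivity_scenarios()]); all by
#'   default.
#' @param horizons numeric years; `Inf` for lifetime.
#' @return tidy data.frame (scenario, horizon, measure, value).
#' @export
run_sensitivity_suite <- function(bundle, scenarios = sensitivity_scenarios(),
                                  horizons = c(5, 10, Inf)) {
  rows <- lapply(scenarios, function(nm) {
    b <- apply_scenario(bundle, nm)
    s <- run_analysis(b, horizons = horizons)$economics$summary
    cbind(scenario = nm, s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness plane from a sensitivity table
#'
#' @param sens output of [run_sensitivity_suite()].
#' @param horizon horizon label to plot (e.g. `"10y"`).
#' @param thresholds WHO thresholds (US$/HALY) drawn as reference lines.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(sens, horizon = "10y",
                          thresholds = c(1720, 5161)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- sens[sens$horizon == horizon &
              sens$measure %in% c("halys_gained", "net_cost"), ]
  w <- reshape(d, idvar = "scenario", timevar = "measure", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  ggplot2::ggplot(w, ggplot2::aes(x = halys_gained, y = net_cost / 1e6,
                                  label = scenario)) +
    ggplot2::geom_abline(intercept = 0, slope = thresholds[1] / 1e6,
                         linetype = "dashed") +
    ggplot2::geom_abline(intercept = 0, slope = thresholds[2] / 1e6,
                         linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "HALYs gained", y = "Net cost (million US$)",
                  title = sprintf("Cost-effectiveness plane (%s)", horizon))
}
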