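# Illness-death consistency: case fatality derivation from prevalence and
# cause-specific mortality, with a forward ODE simulator used as oracle and
# diagnostic.  Remission from IHD is fixed at zero (chronic disease).

#' Case fatality from prevalence and cause-specific mortality
#'
#' The stationary illness-death identity: the cause-specific mortality rate
#' in the whole population equals case fatality times prevalence, so
#' `f = csmr / prevalence` (deaths among cases per case-year).
#'
#' @param prevalence proportion(s) diseased, in \[0, 1\].
#' @param csmr cause-specific mortality rate(s), per person-year.
#' @return case fatality rate(s), per case-year; 0 where both inputs are 0.
#' @export
case_fatality_from_csmr <- function(prevalence, csmr) {
  if (length(prevalence) != length(csmr)) {
    stop("prevalence and csmr must have equal length", call. = FALSE)
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (any(csmr < 0)) stop("csmr must be non-negative", call. = FALSE)
  bad <- prevalence == 0 & csmr > 0
  if (any(bad)) {
    stop(sprintf("inconsistent inputs at index %d: csmr > 0 with prevalence 0",
                 which(bad)[1]), call. = FALSE)
  }
  ifelse(prevalence > 0, csmr / prevalence, 0)
}

#' Derive the case fatality schedule for a bundle
#'
#' @param bundle a `tfa_bundle`.
#' @return data.frame (`sex`, `age`, `case_fatality`), single years of age.
#' @export
derive_case_fatality <- function(bundle) {
  r <- bundle$rates
  data.frame(sex = r$sex, age = r$age,
             case_fatality = case_fatality_from_csmr(r$prevalence, r$csmr),
             stringsAsFactors = FALSE)
}

#' Forward-simulate an illness-death cohort
#'
#' Integrates the chronic-disease illness-death system with remission 0,
#'   dS_h/da = -(i + m_b) S_h,
#'   dS_d/da =  i S_h - (m_b + f) S_d,
#' using within-year constant rates solved in closed form.  States start at
#' age `start_age` with `init_prevalence` diseased and the rest healthy.
#'
#' @param incidence,case_fatality,background_mortality rate vectors indexed
#'   by age `start_age:end_age` (the last value is unused: states are
#'   reported at exact ages).
#' @param start_age,end_age integer ages.
#' @param init_prevalence initial diseased proportion.
#' @return data.frame with columns `age`, `healthy`, `diseased`, `dead`
#'   (cohort proportions), `prevalence` and `csmr` (`= f * prevalence`).
#' @export
simulate_illness_death <- function(incidence, case_fatality,
                                   background_mortality,
                                   start_age = 20L, end_age = 100L,
                                   init_prevalence = 0) {
  ages <- start_age:end_age
  n <- length(ages)
  for (v in list(incidence, case_fatality, background_mortality)) {
    if (length(v) != n) {
      stop("rate vectors must have one value per age in start_age:end_age",
           call. = FALSE)
    }
    if (any(v < 0)) stop("rates must be non-negative", call. = FALSE)
  }
  Sh <- Sd <- dead <- numeric(n)
  Sh[1] <- 1 - init_prevalence
  Sd[1] <- init_prevalence
  for (k in seq_len(n - 1)) {
    i <- incidence[k]; f <- case_fatality[k]; m <- background_mortality[k]
    sh <- Sh[k]; sd_ <- Sd[k]
    Sh[k + 1] <- sh * exp(-(i + m))
    transfer <- if (abs(i - f) < 1e-12) i * exp(-i) else
      i * (exp(-f) - exp(-i)) / (i - f)
    Sd[k + 1] <- exp(-m) * (sd_ * exp(-f) + sh * transfer)
    dead[k + 1] <- dead[k] + (sh + sd_) - (Sh[k + 1] + Sd[k + 1])
  }
  alive <- Sh + Sd
  prev <- ifelse(alive > 0, Sd / alive, 0)
  data.frame(age = ages, healthy = Sh, diseased = Sd, dead = dead,
             prevalence = prev, csmr = case_fatality * prev)
}

#' Epidemiological consistency diagnostics
#'
#' Forward-simulates each sex with the input incidence, derived case
#' fatality and background (non-IHD) mortality, then reports the deviation
#' of the reproduced prevalence and cause-specific mortality from the
#' inputs.  Strata whose relative deviation exceeds `tolerance` (where the
#' input prevalence exceeds `min_prevalence`) are flagged.
#'
#' The comparison is made at five-year-band resolution (the resolution the
#' inputs carry): input and reproduced prevalence/CSMR are averaged over
#' each band before the relative deviation is formed, so within-band
#' growth of a banded input does not register as inconsistency.
#'
#' @param bundle a `tfa_bundle`.
#' @param cf case fatality schedule from [derive_case_fatality()]; derived
#'   if `NULL`.
#' @param tolerance relative deviation beyond which a stratum is flagged.
#' @param min_prevalence band-mean prevalence floor below which deviations
#'   are ignored.
#' @return data.frame (`sex`, `age_group`, `input_prevalence`,
#'   `reproduced_prevalence`, `input_csmr`, `reproduced_csmr`, `deviation`,
#'   `flagged`) with attribute `max_deviation`.
#' @export
consistency_report <- function(bundle, cf = NULL, tolerance = 0.10,
                               min_prevalence = 1e-4) {
  if (is.null(cf)) cf <- derive_case_fatality(bundle)
  bands <- input_bands()
  starts <- band_start(bands)
  out <- do.call(rbind, lapply(SEXES, function(s) {
    r <- bundle$rates[bundle$rates$sex == s, ]
    fs <- cf$case_fatality[cf$sex == s]
    # background = all-cause minus the IHD cause-specific component
    mb <- pmax(r$mortality - r$csmr, 0)
    sim <- simulate_illness_death(r$incidence, fs, mb,
                                  start_age = AGE_MIN, end_age = AGE_MAX,
                                  init_prevalence = r$prevalence[1])
    band_mean <- function(x) {
      vapply(starts, function(a) mean(x[r$age >= a & r$age <= a + 4]),
             numeric(1))
    }
    ip <- band_mean(r$prevalence)
    rp <- band_mean(sim$prevalence)
    ic <- band_mean(r$csmr)
    rc <- band_mean(sim$csmr)
    dev_p <- ifelse(ip > min_prevalence, abs(rp - ip) / ip, 0)
    dev_c <- ifelse(ic > 0 & ip > min_prevalence, abs(rc - ic) / ic, 0)
    dev <- pmax(dev_p, dev_c)
    data.frame(sex = s, age_group = bands,
               input_prevalence = ip, reproduced_prevalence = rp,
               input_csmr = ic, reproduced_csmr = rc,
               deviation = dev, flagged = dev > tolerance,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "max_deviation") <- max(out$deviation)
  out
}
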