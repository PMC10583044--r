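# Independent oracles kept deliberately naive.

# Brute-force three-state discrete Markov chain (well / IHD / dead) with
# background mortality mb acting on both live states and case fatality f
# on the diseased.  Fine time steps; exact competing-risk splits within a
# step.  Returns per-year deaths, year-average prevalence and year-start
# prevalence for a cohort of size 1.
chain_cohort <- function(i, f, mb, years, dt = 1 / 12, p0 = 0) {
  steps <- round(1 / dt)
  W <- 1 - p0
  D <- p0
  deaths <- prev_avg <- prev_start <- numeric(years)
  for (y in seq_len(years)) {
    prev_start[y] <- if (W + D > 0) D / (W + D) else 0
    d_year <- 0
    p_acc <- 0
    for (k in seq_len(steps)) {
      exitW <- W * (1 - exp(-(i + mb) * dt))
      toD <- if (i + mb > 0) exitW * i / (i + mb) else 0
      dW <- exitW - toD
      dD <- D * (1 - exp(-(mb + f) * dt))
      fD <- if (mb + f > 0) dD * f / (mb + f) else 0
      W <- W - exitW
      D <- D + toD - dD
      d_year <- d_year + dW + dD
      p_acc <- p_acc + if (W + D > 0) D / (W + D) else 0
    }
    deaths[y] <- d_year
    prev_avg[y] <- p_acc / steps
  }
  list(deaths = deaths, prev_avg = prev_avg, prev_start = prev_start)
}

# Monte Carlo estimate of the population-average relative risk over a
# truncated lognormal intake distribution (rejection sampling), and the
# attributable fraction it implies.
mc_paf <- function(mean, sd, rr_per_2E, upper, n = 1e6, seed = 1234) {
  set.seed(seed)
  p <- lognormal_params(mean, sd)
  draws <- numeric(0)
  while (length(draws) < n) {
    x <- rlnorm(n, p$meanlog, p$sdlog)
    draws <- c(draws, x[x <= upper])
  }
  draws <- draws[seq_len(n)]
  a <- mean(rr_per_2E^(draws / 2))
  (a - 1) / a
}
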