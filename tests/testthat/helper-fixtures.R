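# Shared fixtures, all built in code.

# constant-temperature weather: convenient for arithmetic-forced GDD cases
const_weather <- function(n_days, tmin = 15, tmax = 25, srad = 15,
                          start_doy = 100L) {
  data.frame(date = NA_character_,
             doy = seq.int(start_doy, length.out = n_days),
             tmin = tmin, tmax = tmax, srad = srad)
}

# season-scale weather reused across model tests
season_weather <- function(seed = 1L) {
  generate_weather(220, seed = seed, start_doy = 120)
}

# one-parameter identity pseudo-model: sim(theta) = theta as "LAI", PNA held
# at zero on both sides, so the likelihood reduces to -(y - theta)^2 / s1^2
pseudo_loglik <- function(y, s1) {
  obs <- observation_set("flowering", 200L, o1 = y, o2 = 0,
                         sigma1 = s1, sigma2 = 1)
  function(theta) {
    log_likelihood(list(lai = theta[[1L]], pna = 0), obs)
  }
}

# moments of a normal(mu, sd) truncated to [lo, hi]
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}
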