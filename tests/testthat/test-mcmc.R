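test_that("initialization draws uniformly within bounds", {
  sp_deg <- parameter_space(c(x = 2), c(x = 2))
  set.seed(1)
  expect_equal(init_theta(sp_deg), c(x = 2))

  sp <- parameter_space(c(x = 0), c(x = 1))
  set.seed(7)
  draws <- replicate(10000, init_theta(sp))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)

  set.seed(123); a <- init_theta(sp)
  set.seed(123); b <- init_theta(sp)
  expect_identical(a, b)
})

test_that("proposal step is bounded, symmetric, and reflects at bounds", {
  sp <- parameter_space(c(x = 0), c(x = 10), D = 5)
  # |raw step| <= (max - min)/D = 2 always, so from the midpoint the
  # proposal never needs reflection and stays within 2 units
  set.seed(3)
  from_mid <- replicate(5000, propose_theta(c(x = 5), sp))
  expect_true(all(abs(from_mid - 5) <= 2 + 1e-12))

  # near-zero step in the D -> infinity limit
  sp_big <- parameter_space(c(x = 0), c(x = 10), D = 1e12)
  expect_equal(propose_theta(c(x = 5), sp_big), c(x = 5), tolerance = 1e-9)

  # symmetry of steps about zero (sign test)
  steps <- from_mid - 5
  n_pos <- sum(steps > 0)
  p <- binom.test(n_pos, length(steps))$p.value
  expect_gt(p, 0.01)

  # reflection keeps proposals inside even from a corner
  set.seed(5)
  at_edge <- replicate(5000, propose_theta(c(x = 0.01), sp))
  expect_true(all(at_edge >= 0 & at_edge <= 10))

  # literal audit variant: strictly non-negative raw steps
  set.seed(6)
  lit <- replicate(2000, propose_theta(c(x = 5), sp, literal = TRUE))
  expect_true(all(lit >= 5))
})

test_that("log-likelihood matches the printed double-sum form", {
  obs <- observation_set(c("tilling", "jointing"), c(170L, 190L),
                         o1 = c(1, 3), o2 = c(5, 20),
                         sigma1 = 0.4, sigma2 = 6)
  expect_equal(log_likelihood(list(lai = c(1, 3), pna = c(5, 20)), obs), 0)

  one <- observation_set("tilling", 170L, o1 = 2, o2 = 10,
                         sigma1 = 0.5, sigma2 = 3)
  # O1 - S1 = sigma1 and O2 = S2: exponent is exactly -1
  expect_equal(log_likelihood(list(lai = 2.5, pna = 10), one), -1)

  # brute-force term-by-term oracle on random vectors
  set.seed(31)
  for (i in 1:20) {
    nT <- sample(2:6, 1)
    o1 <- runif(nT, 0, 8); o2 <- runif(nT, 0, 150)
    s1 <- runif(nT, 0, 8); s2 <- runif(nT, 0, 150)
    sg1 <- runif(1, 0.1, 2); sg2 <- runif(1, 1, 20)
    ob <- observation_set(paste0("s", seq_len(nT)), 150L + seq_len(nT),
                          o1, o2, sg1, sg2)
    acc <- 0
    for (t in seq_len(nT)) {
      acc <- acc - (o1[t] - s1[t])^2 / sg1^2 - (o2[t] - s2[t])^2 / sg2^2
    }
    expect_equal(log_likelihood(list(lai = s1, pna = s2), ob), acc)
  }

  expect_error(log_likelihood(list(lai = 1, pna = 1), obs), "mismatch")
  expect_error(observation_set("a", 1L, 1, 1, sigma1 = 0, sigma2 = 1),
               "positive")

  # the optional Gaussian 1/2 factor halves the exponent
  expect_equal(log_likelihood(list(lai = 2.5, pna = 10), one,
                              gaussian_half = TRUE), -0.5)
})

test_that("acceptance ratio and M-H decision follow min(1, exp(delta)) with ties accepted", {
  expect_equal(acceptance_ratio(-5, -5), 1)
  expect_equal(acceptance_ratio(-5 - log(2), -5), 0.5)
  expect_equal(acceptance_ratio(-1, -7), 1)   # uphill: clamped at 1
  expect_error(acceptance_ratio(NaN, -1), "NaN")

  expect_true(mh_accept(1, 0.999999))
  expect_false(mh_accept(0.5, 0.9))
  expect_true(mh_accept(0.5, 0.5))  # a_p = U ties accept

  # long-run acceptance frequency matches a_p (Bernoulli Monte Carlo)
  set.seed(12)
  for (a_p in c(0.25, 0.7)) {
    u <- runif(20000)
    freq <- mean(mh_accept(a_p, u))
    se <- sqrt(a_p * (1 - a_p) / 20000)
    expect_lt(abs(freq - a_p), 3 * se)
  }
})

test_that("chains are seed-reproducible, length-exact and never leave the bounds", {
  sp <- parameter_space(c(x = 0), c(x = 1), D = 5)
  ll <- pseudo_loglik(y = 0.5, s1 = 0.2)

  ch1 <- run_chain(ll, sp, n_iter = 1, seed = 2)
  expect_equal(ch1$n_iter, 1L)
  expect_equal(nrow(ch1$samples), 1L)

  a <- run_chain(ll, sp, n_iter = 500, seed = 99)
  b <- run_chain(ll, sp, n_iter = 500, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$loglik, b$loglik)

  # bounds invariant under an aggressive proposal scale (D < 1 forces
  # multiple reflections per step)
  sp_wild <- parameter_space(c(x = -2, z = 0), c(x = 3, z = 0.1), D = 0.4)
  flat <- function(theta) 0
  ch <- run_chain(flat, sp_wild, n_iter = 20000, seed = 4)
  expect_true(all(ch$samples[, "x"] >= -2 & ch$samples[, "x"] <= 3))
  expect_true(all(ch$samples[, "z"] >= 0 & ch$samples[, "z"] <= 0.1))
  expect_equal(ch$acceptance_rate, 1)  # flat target accepts everything
})

test_that("flat likelihood recovers the uniform prior over the bounds", {
  sp <- parameter_space(c(x = 2), c(x = 7), D = 5)
  ch <- run_chain(function(theta) 0, sp, n_iter = 10000, seed = 8)
  thin <- ch$samples[seq(2001, 10000, by = 20), "x"]
  ks <- suppressWarnings(ks.test(thin, "punif", 2, 7))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-level discretized target reaches its stationary distribution", {
  # likelihood step: upper half of [0,1] twice as likely as lower half
  sp <- parameter_space(c(x = 0), c(x = 1), D = 5)
  ll <- function(theta) if (theta[[1L]] > 0.5) log(2) else 0
  ch <- run_chain(ll, sp, n_iter = 30000, seed = 17)
  keep <- ch$samples[-(1:2000), "x"]
  p_up <- mean(keep > 0.5)
  ess <- effective_size(as.numeric(keep > 0.5))
  se <- sqrt(2 / 3 * 1 / 3 / ess)
  expect_lt(abs(p_up - 2 / 3), 3 * se)
})

test_that("posterior summary counts, moments and credible intervals are exact", {
  sp <- parameter_space(c(x = 0), c(x = 1))
  ch <- run_chain(pseudo_loglik(0.5, 0.3), sp, n_iter = 3000, seed = 5)
  post <- summarize_chain(ch, burn_in = 1000)
  expect_equal(post$n_retained, 2000L)

  # two-pass oracle on the retained samples
  keep <- ch$samples[1001:3000, "x"]
  expect_equal(post$summary$mean, mean(keep))
  expect_equal(post$summary$var, sum((keep - mean(keep))^2) / (2000 - 1))
  expect_equal(post$summary$lower, unname(quantile(keep, 0.025)))
  expect_equal(post$summary$upper, unname(quantile(keep, 0.975)))

  # constant chain: zero variance, mean at the point
  chc <- ch
  chc$samples[, 1] <- 0.42
  post_c <- summarize_chain(chc, burn_in = 1000)
  expect_equal(post_c$summary$mean, 0.42)
  expect_equal(post_c$summary$var, 0)

  expect_error(summarize_chain(ch, burn_in = 3000), "smaller than")
})

test_that("halving the measurement SDs never inflates the posterior", {
  # identity pseudo-model: posterior sd is sigma/sqrt(2) truncated, so
  # smaller sigma must shrink the sampled posterior variance on average
  sp <- parameter_space(c(x = 0), c(x = 10), D = 5)
  var_at <- function(s1, seed) {
    ch <- run_chain(pseudo_loglik(5, s1), sp, n_iter = 2000, seed = seed)
    summarize_chain(ch, burn_in = 500)$summary$var
  }
  v_wide <- mean(vapply(1:10, function(s) var_at(1.0, s), numeric(1)))
  v_tight <- mean(vapply(1:10, function(s) var_at(0.5, s), numeric(1)))
  expect_lt(v_tight, v_wide)
})
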