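test_that("trapezoid inflation follows the three-stage geometry", {
  sh <- transition_shape(start_year = 2000, len_increase = 10,
                         len_stagnation = 5, len_decrease = 8,
                         max_inflation = 0.08)
  expect_equal(alpha_trapezoid(1999, sh), 0)
  expect_equal(alpha_trapezoid(2000, sh), 0)
  expect_equal(alpha_trapezoid(2005, sh), 0.04)        # halfway up
  expect_equal(alpha_trapezoid(2010, sh), 0.08)        # top reached
  expect_equal(alpha_trapezoid(2012, sh), 0.08)        # stagnation
  expect_equal(alpha_trapezoid(2015, sh), 0.08)        # end of stagnation
  expect_equal(alpha_trapezoid(2019, sh), 0.04)        # halfway down
  expect_equal(alpha_trapezoid(2023, sh), 0)           # closed
  expect_equal(alpha_trapezoid(2028, sh), 0)           # well past

  ## continuity and non-negativity on a fine grid
  tt <- seq(1990, 2035, by = 0.01)
  a <- alpha_trapezoid(tt, sh)
  expect_true(all(a >= 0))
  expect_lt(max(abs(diff(a))), 0.08 / 8 * 0.011)

  ## area under the trapezoid vs adaptive quadrature
  area <- stats::integrate(function(t) alpha_trapezoid(t, sh),
                           1990, 2035, subdivisions = 1000)$value
  expect_equal(area, 0.08 * (10 / 2 + 5 + 8 / 2), tolerance = 1e-4)
})

test_that("expected SRB combines baseline, fluctuation and inflation", {
  expect_equal(srb_mean(b = 1.049, phi = 1, delta = 0, alpha = 0.07), 1.049)
  expect_equal(srb_mean(1.049, 1, 1, 0.05), 1.099)
  ## with no inflation the indicator is irrelevant
  expect_equal(srb_mean(1.049, 1.01, 1, 0), srb_mean(1.049, 1.01, 0, 0))
  expect_true(all(srb_mean(1.049, runif(20, 0.9, 1.1), 1,
                           runif(20, 0, 0.1)) > 0))
})

test_that("AR(1) log density matches the closed-form Gaussian", {
  rho <- 0.85; sig <- 0.1
  set.seed(5)
  phi <- exp(rnorm(6, 0, 0.05))

  ## independent oracle: multivariate normal with the stationary AR(1)
  ## covariance, evaluated from the explicit determinant/quadratic form
  T <- length(phi)
  Sigma <- outer(1:T, 1:T, function(i, j) {
    sig^2 / (1 - rho^2) * rho^abs(i - j)
  })
  x <- log(phi)
  Q <- solve(Sigma)
  oracle <- -T / 2 * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
    0.5 * drop(t(x) %*% Q %*% x)
  expect_equal(ar1_logdensity(phi, rho, sig), oracle, tolerance = 1e-10)

  ## at rho -> 0 the terms become independent normals on the log scale
  expect_equal(ar1_logdensity(phi, 1e-12, sig),
               sum(dnorm(x, 0, sig, log = TRUE)), tolerance = 1e-6)

  ## a constant path at 1 is the product of normal pdfs at zero
  ones <- rep(1, 5)
  expect_equal(ar1_logdensity(ones, rho, sig),
               dnorm(0, 0, sig / sqrt(1 - rho^2), log = TRUE) +
                 4 * dnorm(0, 0, sig, log = TRUE), tolerance = 1e-12)

  expect_error(ar1_logdensity(phi, 1.2, sig), "rho")
})

test_that("AR(1) simulation reproduces the stationary variance", {
  rho <- 0.9; sig <- 0.05
  set.seed(99)
  n <- 200000
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sig / sqrt(1 - rho^2))
  for (t in 2:n) x[t] <- rho * x[t - 1] + sig * rnorm(1)
  expect_equal(var(x), sig^2 / (1 - rho^2), tolerance = 0.05)
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(n / 20))
})

test_that("the start-year prior location tracks the fertility squeeze", {
  tfr <- data.frame(province = "P", year = 2000:2010,
                    tfr = seq(4, 2, length.out = 11))
  ## crosses 3.0 exactly in 2005
  expect_equal(start_year_location(tfr, 3.0), 2005)
  ## an India-like level of 5.2 is crossed immediately here
  expect_equal(start_year_location(tfr, 5.2), 2000)
  ## never crossing: last year, with a warning
  high <- within(tfr, tfr <- tfr + 10)
  expect_warning(y <- start_year_location(high, 3.0), "never")
  expect_equal(y, 2010)
})

test_that("start-year prior is Student-t(3) in shifted-scaled form", {
  loc <- 2004; sc <- 10
  ## independent oracle: explicit gamma-function form of the t(3) density
  t3_pdf <- function(z) {
    exp(lgamma(2) - lgamma(1.5)) / sqrt(3 * pi) * (1 + z^2 / 3)^(-2)
  }
  for (t0 in c(1990, 2000, 2004, 2014, 2030)) {
    z <- (t0 - loc) / sc
    expect_equal(start_year_logprior(t0, loc, sc),
                 log(t3_pdf(z) / sc), tolerance = 1e-10)
  }
  ## symmetric around the location, maximised there
  expect_equal(start_year_logprior(loc - 7, loc, sc),
               start_year_logprior(loc + 7, loc, sc), tolerance = 1e-12)
  expect_gt(start_year_logprior(loc, loc, sc),
            start_year_logprior(loc + 1, loc, sc))
  ## df is pinned to 3 unless explicitly overridden
  expect_error(start_year_logprior(2000, loc, sc, df = 5), "df = 3")
  expect_silent(start_year_logprior(2000, loc, sc, df = 5,
                                    allow_other_df = TRUE))
})

test_that("observation likelihood is lognormal around Theta", {
  ## independent oracle: explicit normal density formula
  r <- 1.10; th <- 1.05; s <- 0.03
  oracle <- -0.5 * log(2 * pi * s^2) - (log(r) - log(th))^2 / (2 * s^2)
  expect_equal(obs_loglik(r, s, th), oracle, tolerance = 1e-10)
  ## at r = theta the density is the normal mode
  expect_equal(obs_loglik(th, s, th), -log(s * sqrt(2 * pi)),
               tolerance = 1e-12)
  ## halving sigma at the mode raises the log density by log 2
  expect_equal(obs_loglik(th, s / 2, th) - obs_loglik(th, s, th), log(2),
               tolerance = 1e-12)
  ## maximised at r = theta
  expect_true(all(obs_loglik(th, s, th) >
                    obs_loglik(th * exp(c(-0.02, 0.02)), s, th)))
  expect_error(obs_loglik(r, 0, th), "positive sampling error")
})

test_that("log posterior equals the sum of independently computed terms", {
  provinces <- c("Province 1", "Province 2")
  years <- 2000:2004
  model <- model_config(years = years, f_star = 3)
  tfr <- tiny_tfr(provinces, years = 1990:2050)
  df <- data.frame(
    province = c("Province 1", "Province 1", "Province 2"),
    source = "S", period_start = c(2000, 2002, 2001),
    period_end = c(2000, 2004, 2003),
    male_births = NA_real_, female_births = NA_real_,
    srb = c(1.06, 1.03, 1.08), log_se = c(0.03, 0.02, 0.05),
    survey_year = 2005)
  df$male_births <- NULL; df$female_births <- NULL
  df$male_births <- c(1060, 1030, 1080); df$female_births <- 1000
  df$srb <- df$male_births / df$female_births
  obs <- as_srb_observations(df, provinces = provinces)

  set.seed(8)
  shp_names <- c("len_increase", "len_stagnation", "len_decrease",
                 "max_inflation")
  state <- list(
    phi = matrix(exp(rnorm(10, 0, 0.005)), 2, 5,
                 dimnames = list(provinces, years)),
    delta = c(1, 0), prob_delta = c(0.6, 0.3),
    t0 = c(2001, 2010), len_increase = c(9, 11),
    len_stagnation = c(4, 6), len_decrease = c(10, 12),
    max_inflation = c(0.07, 0.02),
    hyper_mu = setNames(c(13, 10, 13, 0.05), shp_names),
    hyper_tau = setNames(c(2, 2, 2, 0.01), shp_names))

  ## hand assembly, term by term
  loc1 <- start_year_location(tfr[tfr$province == provinces[1], ], 3)
  loc2 <- start_year_location(tfr[tfr$province == provinces[2], ], 3)
  mids <- period_midpoint_year(df$period_start, df$period_end)
  a1 <- alpha_trapezoid(mids[1:2], transition_shape(2001, 9, 4, 10, 0.07))
  th <- c(model$b * state$phi[1, match(mids[1:2], years)] + 1 * a1,
          model$b * state$phi[2, match(mids[3], years)] + 0)
  hand <- sum(obs_loglik(df$srb, df$log_se, th)) +
    ar1_logdensity(state$phi[1, ], model$rho, model$sigma_ar) +
    ar1_logdensity(state$phi[2, ], model$rho, model$sigma_ar) +
    sum(start_year_logprior(state$t0, c(loc1, loc2), model$t0_scale)) +
    log(0.6) + log(1 - 0.3)
  for (nm in shp_names) {
    h <- model$shape_hyper[[nm]]
    mu <- state$hyper_mu[[nm]]; tau <- state$hyper_tau[[nm]]
    hand <- hand +
      sum(dnorm(state[[nm]], mu, tau, log = TRUE) -
            pnorm(mu / tau, log.p = TRUE)) +
      dnorm(mu, h$m0, h$s0, log = TRUE) +
      log(2) + dnorm(tau, 0, h$tau_scale, log = TRUE)
  }
  expect_equal(log_posterior(state, obs, tfr, model), hand,
               tolerance = 1e-10)

  ## additivity: duplicating an observation adds exactly its likelihood
  obs_dup <- as_srb_observations(rbind(df, df[2, ]),
                                 provinces = provinces)
  expect_equal(log_posterior(state, obs_dup, tfr, model) -
                 log_posterior(state, obs, tfr, model),
               obs_loglik(df$srb[2], df$log_se[2], th[2]),
               tolerance = 1e-10)

  ## permutation invariance of the observation order
  obs_perm <- as_srb_observations(df[c(3, 1, 2), ], provinces = provinces)
  expect_equal(log_posterior(state, obs_perm, tfr, model),
               log_posterior(state, obs, tfr, model), tolerance = 1e-12)

  ## removing all observations leaves the prior-only total
  obs_none <- as_srb_observations(df[0, ], provinces = provinces)
  expect_equal(log_posterior(state, obs_none, tfr, model),
               log_posterior(state, obs, tfr, model) -
                 sum(obs_loglik(df$srb, df$log_se, th)),
               tolerance = 1e-10)
})

test_that("inflation keeps the SRB at or above the fluctuating baseline", {
  fit <- shared_fit()
  th <- srbtrans:::theta_draws(fit)
  base <- fit$model$b * fit$draws$phi
  expect_true(all(th >= base - 1e-12))
})
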