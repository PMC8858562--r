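## Shared fixtures.  Everything is generated in code; the one
## moderately expensive fit is computed lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

## A tiny hand-checkable observation table (2 provinces, 3 observations).
tiny_obs_df <- function() {
  data.frame(
    province = c("Province 1", "Province 1", "Province 2"),
    source = c("Survey 2011", "Survey 2011", "Census 2011"),
    period_start = c(2001, 2006, 2011),
    period_end = c(2005, 2010, 2011),
    male_births = c(1050, 1040, 2100),
    female_births = c(1000, 1000, 2000),
    srb = c(1.05, 1.04, 1.05),
    log_se = c(0.045, 0.045, 0.031),
    survey_year = c(2011, 2011, NA),
    stringsAsFactors = FALSE)
}

## Flat annual TFR covering the default grid and horizon.
tiny_tfr <- function(provinces, years = 1976:2050,
                     tfr_start = 6, tfr_end = 1.9, midpoint = 2000) {
  do.call(rbind, lapply(provinces, function(p) {
    simulate_tfr_series(p, tfr_start, tfr_end, years, midpoint)
  }))
}

## Small but converging default-scenario fit, shared across test files.
shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- simulate_srb_dataset(scenario_config(seed = 42L))
    .fixture_env$dataset <- ds
    .fixture_env$fit <- suppressWarnings(suppressMessages(
      fit_srb_mcmc(ds$observations, ds$tfr,
                   mcmc = mcmc_config(n_chains = 2, n_warmup = 600,
                                      n_samples = 1200, seed = 7L))))
  }
  .fixture_env$fit
}

shared_dataset <- function() {
  shared_fit()
  .fixture_env$dataset
}

## A handcrafted fit-shaped object with fully known draws, for exact
## checks of the summary/projection machinery without MCMC noise.
fake_fit <- function(n_draws = 4, provinces = c("A", "B"),
                     years = 2000:2004,
                     delta = matrix(1, n_draws, length(provinces)),
                     t0 = 2001, len_increase = 2, len_stagnation = 1,
                     len_decrease = 2, max_inflation = 0.06,
                     phi_value = 1, model = model_config(years = years)) {
  P <- length(provinces)
  T <- length(years)
  mk <- function(x) matrix(x, n_draws, P,
                           dimnames = list(NULL, provinces))
  draws <- list(
    phi = array(phi_value, c(n_draws, P, T),
                dimnames = list(NULL, provinces, years)),
    delta = mk(delta), prob_delta = mk(0.5), t0 = mk(t0),
    len_increase = mk(len_increase), len_stagnation = mk(len_stagnation),
    len_decrease = mk(len_decrease), max_inflation = mk(max_inflation),
    hyper_mu = matrix(0, n_draws, 4), hyper_tau = matrix(1, n_draws, 4),
    lp = numeric(n_draws))
  structure(list(draws = draws, chain_id = rep(1L, n_draws),
                 provinces = provinces, years = as.integer(years),
                 model = model,
                 mcmc = mcmc_config(n_chains = 1, n_warmup = 10,
                                    n_samples = max(n_draws, 10)),
                 data = NULL,
                 tfr = tiny_tfr(provinces, years = 1976:2050),
                 diagnostics = NULL),
            class = "srb_fit")
}
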