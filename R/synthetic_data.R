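#' Simulate a smoothly declining total fertility rate series
#'
#' Generates a monotone-decreasing logistic TFR curve from `tfr_start`
#' towards `tfr_end` over the year grid — the canonical shape of a fertility
#' transition and the input the start-year prior needs.
#'
#' @param province province label.
#' @param tfr_start,tfr_end asymptotic TFR levels (children per woman);
#'   `tfr_start >= tfr_end > 0`.
#' @param years integer calendar-year grid.
#' @param midpoint_year year at which the decline is halfway.
#' @param steepness logistic rate per year (> 0); large values approach a
#'   step function at `midpoint_year`.
#' @return data frame `province`, `year`, `tfr` of class `tfr_series`.
#' @export
simulate_tfr_series <- function(province, tfr_start, tfr_end, years,
                                midpoint_year, steepness = 0.12) {
  stopifnot(tfr_end > 0, steepness > 0)
  if (tfr_start < tfr_end) {
    stop("tfr_start must be >= tfr_end (fertility transitions decline)",
         call. = FALSE)
  }
  tfr <- tfr_end + (tfr_start - tfr_end) /
    (1 + exp(steepness * (years - midpoint_year)))
  structure(
    data.frame(province = province, year = as.integer(years), tfr = tfr,
               stringsAsFactors = FALSE),
    class = c("tfr_series", "data.frame"))
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defines a complete ground-truth scenario: the latent-process constants,
#' per-province inflation truth, fertility paths, and the survey/census
#' observation schedule.  Defaults emulate a seven-province Nepal-like
#' setting: baseline 1.049, AR(1) rho 0.9 and innovation sd 0.004 on the
#' log scale, four full-birth-history surveys (2001, 2006, 2011, 2016) each
#' contributing three five-year-period observations per province plus a
#' 2011 census observation, roughly 5,000 births per survey observation
#' spread over 40 sampling clusters, fertility falling from about 6 to
#' about 2 children per woman, and transitions (where present) starting
#' around the turn of the millennium with maximum inflation 0.05 over a
#' 36-year span.
#'
#' @param n_provinces number of provinces.
#' @param years estimation-grid calendar years.
#' @param tfr_years calendar years the TFR series must cover (through the
#'   projection horizon).
#' @param baseline_b national SRB baseline.
#' @param ar1_rho,ar1_sd AR(1) parameters of log(phi).
#' @param delta_truth binary vector: which provinces truly inflate.
#' @param t0_truth,len_increase,len_stagnation,len_decrease,max_inflation
#'   true trapezoid shapes (recycled across provinces).
#' @param tfr_start,tfr_end,tfr_midpoint,tfr_steepness per-province TFR
#'   curve settings (recycled).
#' @param births_per_obs total births underlying one survey observation.
#' @param n_clusters sampling clusters per survey observation.
#' @param survey_years years the retrospective surveys are fielded.
#' @param periods_per_survey number of contiguous multi-year periods each
#'   survey contributes per province.
#' @param period_length length of each period in years.
#' @param census_year year of the census observation (`NA` for none).
#' @param census_births births underlying one census observation.
#' @param seed integer RNG seed.
#' @return a list of class `srb_scenario`.
#' @export
scenario_config <- function(n_provinces = 7,
                            years = 1976:2016,
                            tfr_years = 1976:2050,
                            baseline_b = 1.049,
                            ar1_rho = 0.9,
                            ar1_sd = 0.004,
                            delta_truth = c(1, 0, 1, 0, 1, 0, 1),
                            t0_truth = c(2006, 2017, 2004, 2006, 2001,
                                         2013, 2005),
                            len_increase = 13,
                            len_stagnation = 10,
                            len_decrease = 13,
                            max_inflation = 0.05,
                            tfr_start = c(5.8, 6.2, 5.5, 5.6, 6.0, 6.3, 6.1),
                            tfr_end = 1.9,
                            tfr_midpoint = c(2003, 2014, 2001, 2003, 1998,
                                             2010, 2002),
                            tfr_steepness = 0.12,
                            births_per_obs = 5000,
                            n_clusters = 40,
                            survey_years = c(2001, 2006, 2011, 2016),
                            periods_per_survey = 3,
                            period_length = 5,
                            census_year = 2011,
                            census_births = 7000,
                            seed = 1L) {
  P <- n_provinces
  rec <- function(x) rep_len(x, P)
  stopifnot(ar1_rho > 0, ar1_rho < 1, ar1_sd > 0, baseline_b > 0,
            births_per_obs >= n_clusters, n_clusters >= 2)
  cfg <- list(
    n_provinces = P,
    provinces = paste("Province", seq_len(P)),
    years = as.integer(years),
    tfr_years = as.integer(tfr_years),
    baseline_b = baseline_b,
    ar1_rho = ar1_rho, ar1_sd = ar1_sd,
    delta_truth = rec(delta_truth),
    t0_truth = rec(t0_truth),
    len_increase = rec(len_increase),
    len_stagnation = rec(len_stagnation),
    len_decrease = rec(len_decrease),
    max_inflation = rec(max_inflation),
    tfr_start = rec(tfr_start), tfr_end = rec(tfr_end),
    tfr_midpoint = rec(tfr_midpoint), tfr_steepness = rec(tfr_steepness),
    births_per_obs = births_per_obs, n_clusters = n_clusters,
    survey_years = survey_years,
    periods_per_survey = periods_per_survey,
    period_length = period_length,
    census_year = census_year, census_births = census_births,
    seed = as.integer(seed))
  stopifnot(all(cfg$max_inflation >= 0), all(cfg$len_increase > 0),
            all(cfg$len_stagnation >= 0), all(cfg$len_decrease > 0))
  structure(cfg, class = "srb_scenario")
}

#' Simulate the latent ground truth of a scenario
#'
#' Draws each province's log(phi) path from the AR(1) process (stationary
#' initial value, then the recursion), evaluates the trapezoid inflation
#' alpha from the configured true shapes, and assembles
#' `Theta = b * phi + delta * alpha` exactly.  Also builds the TFR series.
#'
#' @param config an [scenario_config()].
#' @return a list with `theta`, `phi`, `alpha` (province x year matrices),
#'   `delta`, `shapes` (per-province [transition_shape()] list), `tfr`
#'   (combined `tfr_series`), `provinces`, `years`, and the scenario.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "srb_scenario"))
  set.seed(config$seed)
  P <- config$n_provinces
  years <- config$years
  T <- length(years)
  sd_stat <- config$ar1_sd / sqrt(1 - config$ar1_rho^2)

  logphi <- matrix(0, P, T, dimnames = list(config$provinces, years))
  for (p in seq_len(P)) {
    logphi[p, 1] <- rnorm(1, 0, sd_stat)
    for (t in seq_len(T)[-1]) {
      logphi[p, t] <- rnorm(1, config$ar1_rho * logphi[p, t - 1],
                            config$ar1_sd)
    }
  }
  phi <- exp(logphi)

  shapes <- lapply(seq_len(P), function(p) {
    transition_shape(config$t0_truth[p], config$len_increase[p],
                     config$len_stagnation[p], config$len_decrease[p],
                     config$max_inflation[p])
  })
  names(shapes) <- config$provinces
  alpha <- t(vapply(seq_len(P), function(p) {
    alpha_trapezoid(years, shapes[[p]])
  }, numeric(T)))
  dimnames(alpha) <- dimnames(logphi)

  theta <- config$baseline_b * phi + config$delta_truth * alpha

  tfr <- do.call(rbind, lapply(seq_len(P), function(p) {
    simulate_tfr_series(config$provinces[p], config$tfr_start[p],
                        config$tfr_end[p], config$tfr_years,
                        config$tfr_midpoint[p], config$tfr_steepness[p])
  }))

  list(theta = theta, phi = phi, alpha = alpha,
       delta = setNames(config$delta_truth, config$provinces),
       shapes = shapes, tfr = tfr, provinces = config$provinces,
       years = years, config = config)
}

## One clustered survey-style observation at a given true SRB theta:
## births are allocated to clusters multinomially with equal expected
## sizes, male counts are binomial with p = theta / (1 + theta), and the
## sampling error is the delete-one-cluster jackknife.  Degenerate draws
## (zero male or female totals, possible only at tiny sizes) are redrawn.
simulate_cluster_obs <- function(theta, total_births, n_clusters) {
  p_male <- theta / (1 + theta)
  redraws <- 0L
  repeat {
    sizes <- as.vector(rmultinom(1, total_births,
                                 rep(1 / n_clusters, n_clusters)))
    male <- rbinom(n_clusters, sizes, p_male)
    female <- sizes - male
    tm <- sum(male); tf <- sum(female)
    ok <- tm > 0 && tf > 0 &&
      all((tm - male) > 0) && all((tf - female) > 0)
    if (ok) break
    redraws <- redraws + 1L
    if (redraws > 1000L) {
      stop("could not draw a non-degenerate clustered observation",
           call. = FALSE)
    }
  }
  clusters <- data.frame(cluster_id = seq_len(n_clusters),
                         male_births = male, female_births = female)
  list(male = tm, female = tf, srb = tm / tf,
       log_se = jackknife_log_se(clusters), redraws = redraws)
}

#' Simulate survey and census observations from a latent truth
#'
#' For each survey year and each province, generates `periods_per_survey`
#' contiguous multi-year-period observations ending the year before the
#' survey, at the truth's SRB in each period's midpoint year; counts come
#' from the clustered binomial design of the scenario and sampling errors
#' from the delete-one-cluster jackknife.  A single-year census observation
#' is added if the scenario has a `census_year`.
#'
#' @param truth output of [simulate_truth()].
#' @param seed integer seed (defaults to the scenario seed + 1 so truth and
#'   observations are independently reproducible).
#' @return an `srb_obs` observation set.
#' @export
simulate_observations <- function(truth, seed = truth$config$seed + 1L) {
  config <- truth$config
  set.seed(seed)
  years <- config$years
  rows <- list()
  theta_at <- function(p, year) {
    yr <- min(max(year, years[1]), years[length(years)])
    truth$theta[p, as.character(yr)]
  }
  for (sy in config$survey_years) {
    for (p in seq_len(config$n_provinces)) {
      for (k in seq_len(config$periods_per_survey)) {
        period_end <- sy - 1 - (config$periods_per_survey - k) *
          config$period_length
        period_start <- period_end - config$period_length + 1
        if (period_start < years[1]) next
        mid <- period_midpoint_year(period_start, period_end)
        sim <- simulate_cluster_obs(theta_at(p, mid),
                                    config$births_per_obs,
                                    config$n_clusters)
        rows[[length(rows) + 1L]] <- data.frame(
          province = config$provinces[p], source = paste("Survey", sy),
          period_start = period_start, period_end = period_end,
          male_births = sim$male, female_births = sim$female,
          srb = sim$srb, log_se = sim$log_se, survey_year = sy,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.na(config$census_year)) {
    for (p in seq_len(config$n_provinces)) {
      sim <- simulate_cluster_obs(theta_at(p, config$census_year),
                                  config$census_births, config$n_clusters)
      rows[[length(rows) + 1L]] <- data.frame(
        province = config$provinces[p],
        source = paste("Census", config$census_year),
        period_start = config$census_year,
        period_end = config$census_year,
        male_births = sim$male, female_births = sim$female,
        srb = sim$srb, log_se = sim$log_se, survey_year = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  as_srb_observations(do.call(rbind, rows), provinces = config$provinces)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_truth()] then
#' [simulate_observations()] under the scenario's seed.
#'
#' @param config an [scenario_config()].
#' @return list of class `srb_synthetic` with elements `truth`,
#'   `observations`, `tfr`.
#' @export
simulate_srb_dataset <- function(config = scenario_config()) {
  truth <- simulate_truth(config)
  obs <- simulate_observations(truth)
  structure(list(truth = truth, observations = obs, tfr = truth$tfr),
            class = "srb_synthetic")
}
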