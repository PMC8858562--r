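#' Split observations into training and held-out sets by collection year
#'
#' Retrospective birth-history data arrive in series: an out-of-sample
#' exercise therefore holds out whole recently-collected sources rather
#' than random rows.  Observations from surveys fielded in or after
#' `cutoff` form the test set; everything else (including census
#' observations, which carry no survey year) trains the model.  The rule is
#' deterministic.
#'
#' @param data an `srb_obs` observation set with `survey_year` present for
#'   survey rows.
#' @param cutoff first survey year assigned to the test set (default 2016).
#' @return list with elements `train` and `test`, both `srb_obs`, disjoint,
#'   whose union is `data`; also `test_share`, the held-out fraction.
#' @export
holdout_split <- function(data, cutoff = 2016) {
  df <- as.data.frame(data)
  provinces <- attr(data, "provinces")
  in_test <- !is.na(df$survey_year) & df$survey_year >= cutoff
  if (!any(in_test)) {
    stop("holdout cutoff ", cutoff, " leaves the test set empty",
         call. = FALSE)
  }
  if (all(in_test)) {
    stop("holdout cutoff ", cutoff, " leaves the training set empty",
         call. = FALSE)
  }
  train <- as_srb_observations(df[!in_test, , drop = FALSE],
                               provinces = provinces)
  test <- as_srb_observations(df[in_test, , drop = FALSE],
                              provinces = provinces)
  list(train = train, test = test, test_share = mean(in_test))
}

#' Posterior predictive intervals for held-out observations
#'
#' The predictive distribution of a held-out log ratio is the posterior of
#' log(Theta) at the observation's midpoint year plus independent
#' N(0, sigma^2) observation noise, sigma being the observation's own
#' sampling error.
#'
#' @param fit an `srb_fit` trained without the held-out rows.
#' @param test_obs held-out observation set; every row's province must be in
#'   the fit and its midpoint year on the estimation grid.
#' @param levels nominal central interval levels (default 80% and 95%).
#' @param seed RNG seed for the observation-noise draws.
#' @return data frame, one row per test observation: `province`, `year`,
#'   `log_r`, `median_pred` (median predicted log ratio), and
#'   `lower_<level>` / `upper_<level>` per level.
#' @export
predictive_intervals <- function(fit, test_obs, levels = c(0.8, 0.95),
                                 seed = 1L) {
  stopifnot(inherits(fit, "srb_fit"))
  df <- as.data.frame(test_obs)
  if (!all(df$province %in% fit$provinces)) {
    stop("held-out observation province(s) without a fitted state: ",
         paste(setdiff(df$province, fit$provinces), collapse = ", "),
         call. = FALSE)
  }
  t_mid <- period_midpoint_year(df$period_start, df$period_end)
  if (!all(t_mid %in% fit$years)) {
    stop("held-out observation midpoint year(s) outside the model grid",
         call. = FALSE)
  }
  th <- theta_draws(fit)
  nd <- dim(th)[1]
  set.seed(seed)
  out <- data.frame(province = df$province, year = t_mid,
                    log_r = log(df$srb),
                    median_pred = NA_real_, stringsAsFactors = FALSE)
  for (lv in levels) {
    out[[paste0("lower_", lv)]] <- NA_real_
    out[[paste0("upper_", lv)]] <- NA_real_
  }
  for (i in seq_len(nrow(df))) {
    p <- match(df$province[i], fit$provinces)
    t <- match(t_mid[i], fit$years)
    pred <- log(th[, p, t]) + rnorm(nd, 0, df$log_se[i])
    out$median_pred[i] <- median(pred)
    for (lv in levels) {
      a <- (1 - lv) / 2
      out[[paste0("lower_", lv)]][i] <- quantile(pred, a, names = FALSE)
      out[[paste0("upper_", lv)]][i] <- quantile(pred, 1 - a,
                                                 names = FALSE)
    }
  }
  attr(out, "levels") <- levels
  out
}

#' Out-of-sample calibration metrics
#'
#' Compares held-out log ratios with their posterior predictive intervals:
#' empirical coverage per nominal level, and median / mean / mean-absolute
#' prediction errors on the log scale.  A well-specified model yields
#' empirical coverage at or (when intervals are conservative) above the
#' nominal level.
#'
#' @param test_obs the held-out observation set.
#' @param predictive output of [predictive_intervals()] for exactly those
#'   observations.
#' @return list of class `srb_validation`: `n_test`, `coverage` (named by
#'   level), `median_error`, `mean_error`, `mean_abs_error`, and
#'   `per_province` breakdown.
#' @export
coverage_metrics <- function(test_obs, predictive) {
  df <- as.data.frame(test_obs)
  if (nrow(df) != nrow(predictive) ||
      !all(df$province == predictive$province)) {
    stop("test observations and predictive intervals do not match row ",
         "for row", call. = FALSE)
  }
  levels <- attr(predictive, "levels")
  err <- log(df$srb) - predictive$median_pred
  covered <- sapply(levels, function(lv) {
    predictive$log_r >= predictive[[paste0("lower_", lv)]] &
      predictive$log_r <= predictive[[paste0("upper_", lv)]]
  })
  if (is.null(dim(covered))) covered <- matrix(covered, nrow = nrow(df))
  colnames(covered) <- paste0("coverage_", levels)
  per_prov <- stats::aggregate(
    cbind(covered, abs_error = abs(err)),
    by = list(province = df$province), FUN = mean)
  structure(list(
    n_test = nrow(df),
    coverage = setNames(colMeans(covered), colnames(covered)),
    median_error = median(err),
    mean_error = mean(err),
    mean_abs_error = mean(abs(err)),
    per_province = per_prov),
    class = "srb_validation")
}

## Draw ground-truth shapes and indicators from the model prior, so that
## credible-interval coverage in the recovery study is a proper Bayesian
## calibration check.  Returns a modified scenario.
randomize_scenario_shapes <- function(scenario, model, seed,
                                      randomize_delta = FALSE) {
  set.seed(seed)
  P <- scenario$n_provinces
  hy <- model$shape_hyper
  draw_tn <- function(m0, s0, tau_scale, lower = 0) {
    mu <- rnorm(1, m0, s0)
    tau <- abs(rnorm(1, 0, tau_scale))
    x <- numeric(P)
    for (p in seq_len(P)) {
      repeat {
        x[p] <- rnorm(1, mu, tau)
        if (x[p] > lower) break
      }
    }
    x
  }
  scenario$len_increase <- draw_tn(hy$len_increase$m0, hy$len_increase$s0,
                                   hy$len_increase$tau_scale)
  scenario$len_stagnation <- draw_tn(hy$len_stagnation$m0,
                                     hy$len_stagnation$s0,
                                     hy$len_stagnation$tau_scale)
  scenario$len_decrease <- draw_tn(hy$len_decrease$m0, hy$len_decrease$s0,
                                   hy$len_decrease$tau_scale)
  scenario$max_inflation <- draw_tn(hy$max_inflation$m0,
                                    hy$max_inflation$s0,
                                    hy$max_inflation$tau_scale)
  loc <- vapply(seq_len(P), function(p) {
    tp <- simulate_tfr_series(scenario$provinces[p], scenario$tfr_start[p],
                              scenario$tfr_end[p], scenario$tfr_years,
                              scenario$tfr_midpoint[p],
                              scenario$tfr_steepness[p])
    start_year_location(tp, model$f_star)
  }, numeric(1))
  t0 <- loc + model$t0_scale * stats::rt(P, df = 3)
  scenario$t0_truth <- pmin(pmax(t0, model$t0_window[1]),
                            model$t0_window[2])
  if (randomize_delta) {
    scenario$delta_truth <- rbinom(P, 1, 0.5)
  }
  scenario
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates a synthetic dataset, fits the model, and scores how
#' well the posterior recovers the known truth: credible-interval coverage
#' and error of Theta over all province-years, conditional coverage of the
#' maximum inflation and start year in truly-inflating provinces, and the
#' classification of the inflation indicator (posterior probability on the
#' correct side of 0.5).  Replicates whose sampler fails the convergence
#' check are excluded from the aggregates and counted.
#'
#' @param scenario an [scenario_config()] defining the data-generating
#'   conditions.
#' @param n_replicates number of simulate-fit replicates.
#' @param model a [model_config()]; its grid must equal the scenario's.
#' @param mcmc an [mcmc_config()] (reduced draws are fine and are recorded
#'   in the report).
#' @param seed master seed; replicate r uses `seed + r` for its data.
#' @param randomize_shapes draw each replicate's true shapes from the model
#'   prior (default `TRUE`), making coverage a calibration check; set
#'   `FALSE` to keep the scenario's fixed shapes.
#' @param randomize_delta also draw the true indicators Bernoulli(0.5).
#' @return list of class `srb_recovery`: per-replicate table and aggregate
#'   `theta_coverage_95`, `theta_bias`, `theta_rmse`, `delta_accuracy`,
#'   `xi_coverage_95`, `t0_coverage_95`, `n_excluded`, `n_replicates`,
#'   plus the Monte-Carlo standard error of the Theta coverage.
#' @export
simulation_study <- function(scenario, n_replicates, model = model_config(),
                             mcmc = mcmc_config(), seed = 1L,
                             randomize_shapes = TRUE,
                             randomize_delta = FALSE) {
  reps <- vector("list", n_replicates)
  n_excluded <- 0L
  for (r in seq_len(n_replicates)) {
    sc <- scenario
    sc$seed <- as.integer(seed + r)
    if (randomize_shapes) {
      sc <- randomize_scenario_shapes(sc, model, seed = seed + 10000L + r,
                                      randomize_delta = randomize_delta)
    }
    ds <- simulate_srb_dataset(sc)
    mc <- mcmc
    mc$seed <- as.integer(seed + 20000L + r)
    fit <- suppressWarnings(
      fit_srb_mcmc(ds$observations, ds$tfr, model = model, mcmc = mc))
    if (!isTRUE(fit$converged)) {
      n_excluded <- n_excluded + 1L
      next
    }
    th <- theta_draws(fit)
    qlo <- apply(th, c(2, 3), quantile, 0.025, names = FALSE)
    qhi <- apply(th, c(2, 3), quantile, 0.975, names = FALSE)
    qmed <- apply(th, c(2, 3), median)
    truth_th <- ds$truth$theta
    cover <- mean(truth_th >= qlo & truth_th <= qhi)
    bias <- mean(qmed - truth_th)
    rmse <- sqrt(mean((qmed - truth_th)^2))
    prob <- inflation_probability(fit)
    delta_true <- ds$truth$delta
    correct <- (prob > 0.5 & delta_true == 1) |
      (prob < 0.5 & delta_true == 0)
    ## conditional recovery of xi and t0 where inflation truly occurred
    xi_cov <- t0_cov <- NA_real_
    inf_p <- which(delta_true == 1)
    if (length(inf_p) > 0L) {
      cond_cover <- function(draw_mat, truth_vec) {
        vapply(inf_p, function(p) {
          sel <- fit$draws$delta[, p] == 1
          if (sum(sel) < 20) return(NA)
          q <- quantile(draw_mat[sel, p], c(0.025, 0.975), names = FALSE)
          truth_vec[p] >= q[1] && truth_vec[p] <= q[2]
        }, logical(1))
      }
      xi_cov <- mean(cond_cover(fit$draws$max_inflation,
                                sc$max_inflation), na.rm = TRUE)
      t0_cov <- mean(cond_cover(fit$draws$t0, sc$t0_truth), na.rm = TRUE)
    }
    reps[[r]] <- data.frame(
      replicate = r, theta_coverage_95 = cover, theta_bias = bias,
      theta_rmse = rmse, delta_accuracy = mean(correct),
      xi_coverage_95 = xi_cov, t0_coverage_95 = t0_cov,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("no replicate passed the convergence check", call. = FALSE)
  }
  cov_mean <- mean(tab$theta_coverage_95)
  structure(list(
    replicates = tab,
    theta_coverage_95 = cov_mean,
    theta_coverage_se = sd(tab$theta_coverage_95) / sqrt(nrow(tab)),
    theta_bias = mean(tab$theta_bias),
    theta_rmse = mean(tab$theta_rmse),
    delta_accuracy = mean(tab$delta_accuracy),
    xi_coverage_95 = mean(tab$xi_coverage_95, na.rm = TRUE),
    t0_coverage_95 = mean(tab$t0_coverage_95, na.rm = TRUE),
    n_excluded = n_excluded,
    n_replicates = n_replicates,
    mcmc = mcmc),
    class = "srb_recovery")
}
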