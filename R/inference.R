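#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler.  Random-walk proposal
#' scales are adapted towards a 44% acceptance rate during warmup and
#' frozen afterwards.
#'
#' @param n_chains number of independent chains (run sequentially under one
#'   seed stream, so the full fit is reproducible).
#' @param n_warmup adaptation iterations per chain (discarded).
#' @param n_samples post-warmup iterations per chain.
#' @param thin store every `thin`-th post-warmup iteration; must divide
#'   `n_samples`.
#' @param seed integer RNG seed, recorded in the fit.
#' @param rhat_threshold split-R-hat above which the fit completes with a
#'   prominent warning.
#' @param ess_threshold smallest acceptable effective sample size per
#'   monitored scalar.
#' @return a list of class `srb_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_warmup = 1000, n_samples = 2000,
                        thin = 1, seed = 1L, rhat_threshold = 1.05,
                        ess_threshold = 200) {
  stopifnot(n_chains >= 1, n_warmup >= 10, n_samples >= 10, thin >= 1,
            n_samples %% thin == 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold),
            class = "srb_mcmc_config")
}

## Sum a per-observation vector into a per-province vector.
sum_by_province <- function(x, p_idx, P) {
  out <- numeric(P)
  if (length(x) > 0L) {
    s <- rowsum(x, p_idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' Fit the hierarchical SRB model by MCMC
#'
#' Samples the posterior defined by [log_posterior()] with a
#' Metropolis-within-Gibbs scheme: single-site adaptive random-walk updates
#' of the log AR(1) path (vectorised across provinces), adaptive random-walk
#' updates of the trapezoid shape parameters and the shape hyperparameters,
#' an exact two-point Gibbs step for each province's inflation indicator
#' delta (conditional odds = prior odds times the likelihood ratio with the
#' trapezoid on versus off), and a conjugate Beta step for the
#' indicator means.  Shape parameters are retained and updated from their
#' prior while delta = 0, keeping the chain irreducible (standard
#' spike-and-slab practice).
#'
#' @param data an `srb_obs` observation set (preprocessed: positive
#'   `log_se` everywhere).
#' @param tfr data frame `province`, `year`, `tfr` covering every province
#'   in `data` through any horizon whose fertility level should inform the
#'   start-year prior.
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()].
#' @return an object of class `srb_fit`: posterior draws of all latent
#'   quantities, convergence diagnostics (split R-hat, effective sample
#'   size), acceptance rates, and the inputs.
#' @export
fit_srb_mcmc <- function(data, tfr, model = model_config(),
                         mcmc = mcmc_config()) {
  stopifnot(inherits(model, "srb_model_config"),
            inherits(mcmc, "srb_mcmc_config"))
  df <- as.data.frame(data)
  provinces <- attr(data, "provinces")
  if (is.null(provinces)) provinces <- unique(df$province)
  P <- length(provinces)
  years <- model$years
  T <- length(years)
  b <- model$b; rho <- model$rho; sig <- model$sigma_ar
  sd_stat <- sig / sqrt(1 - rho^2)

  ## observation bookkeeping
  n_obs <- nrow(df)
  if (n_obs > 0L && any(!(df$log_se > 0))) {
    stop("all observations must carry positive sampling errors",
         call. = FALSE)
  }
  p_idx <- match(df$province, provinces)
  t_mid <- period_midpoint_year(df$period_start, df$period_end)
  t_idx <- match(t_mid, years)
  if (n_obs > 0L && any(is.na(t_idx))) {
    stop("observation midpoint year(s) outside the model grid: ",
         paste(unique(t_mid[is.na(t_idx)]), collapse = ", "), call. = FALSE)
  }
  logr <- log(df$srb)
  sigma <- df$log_se
  ## checkerboard split of the path update: odd and even years form
  ## conditionally independent blocks given each other, so each half is
  ## updated in one vectorised move
  obs_by_p <- lapply(seq_len(P), function(p) which(p_idx == p))
  parity_sets <- lapply(0:1, function(par) {
    ts <- seq_len(T)[seq_len(T) %% 2L == par]
    rows <- which(t_idx %in% ts)
    list(ts = ts, rows = rows,
         site = match(t_idx[rows], ts),
         has_prev = ts > 1L, has_next = ts < T)
  })

  ## start-year prior locations from the fertility squeeze
  loc <- vapply(provinces, function(p) {
    tp <- tfr[tfr$province == p, , drop = FALSE]
    if (nrow(tp) == 0L) {
      stop("no TFR series for province ", p, call. = FALSE)
    }
    start_year_location(tp[order(tp$year), ], model$f_star)
  }, numeric(1))

  shp_names <- c("len_increase", "len_stagnation", "len_decrease",
                 "max_inflation")
  hy <- model$shape_hyper
  m0 <- vapply(shp_names, function(nm) hy[[nm]]$m0, numeric(1))
  s0 <- vapply(shp_names, function(nm) hy[[nm]]$s0, numeric(1))
  tau_scale <- vapply(shp_names, function(nm) hy[[nm]]$tau_scale,
                      numeric(1))

  n_store_chain <- mcmc$n_samples %/% mcmc$thin
  n_store <- mcmc$n_chains * n_store_chain
  store <- list(
    phi = array(NA_real_, c(n_store, P, T),
                dimnames = list(NULL, provinces, years)),
    delta = matrix(NA_real_, n_store, P, dimnames = list(NULL, provinces)),
    prob_delta = matrix(NA_real_, n_store, P,
                        dimnames = list(NULL, provinces)),
    t0 = matrix(NA_real_, n_store, P, dimnames = list(NULL, provinces)),
    len_increase = matrix(NA_real_, n_store, P,
                          dimnames = list(NULL, provinces)),
    len_stagnation = matrix(NA_real_, n_store, P,
                            dimnames = list(NULL, provinces)),
    len_decrease = matrix(NA_real_, n_store, P,
                          dimnames = list(NULL, provinces)),
    max_inflation = matrix(NA_real_, n_store, P,
                           dimnames = list(NULL, provinces)),
    hyper_mu = matrix(NA_real_, n_store, 4,
                      dimnames = list(NULL, shp_names)),
    hyper_tau = matrix(NA_real_, n_store, 4,
                       dimnames = list(NULL, shp_names)),
    lp = numeric(n_store))
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_store_chain)

  set.seed(mcmc$seed)
  acc_tot <- c(phi = 0, shape = 0, hyper = 0)
  acc_n <- c(phi = 0, shape = 0, hyper = 0)
  row_at <- 0L

  for (chain in seq_len(mcmc$n_chains)) {
    ## --- initial state (chains overdispersed via the seed stream)
    logphi <- matrix(rnorm(P * T, 0, sd_stat), P, T)
    delta <- rep(1, P)
    prob_delta <- rep(0.5, P)
    t0 <- pmin(pmax(loc + rnorm(P, 0, 2), model$t0_window[1]),
               model$t0_window[2])
    shp <- list(len_increase = pmax(m0[1] + rnorm(P, 0, 1), 1),
                len_stagnation = pmax(m0[2] + rnorm(P, 0, 1), 0.5),
                len_decrease = pmax(m0[3] + rnorm(P, 0, 1), 1),
                max_inflation = pmax(m0[4] + rnorm(P, 0, m0[4] / 4),
                                     1e-4))
    hyper_mu <- m0
    hyper_tau <- tau_scale / 2
    names(hyper_mu) <- names(hyper_tau) <- shp_names

    ## proposal scales (adapted in warmup, frozen after)
    sc_phi <- matrix(max(sig, 1e-3) * 2, P, T)
    beta_pcn <- rep(0.5, P)
    sc_shape <- list(t0 = rep(4, P), len_increase = rep(2, P),
                     len_stagnation = rep(2, P), len_decrease = rep(2, P),
                     max_inflation = rep(0.02, P))
    sc_hyper_tau <- tau_scale / 2

    alpha_obs <- alpha_tz(t_mid, t0[p_idx], shp$len_increase[p_idx],
                          shp$len_stagnation[p_idx],
                          shp$len_decrease[p_idx],
                          shp$max_inflation[p_idx])

    shape_prior <- function(nm, val) {
      if (nm == "t0") {
        out <- start_year_logprior(val, loc, model$t0_scale)
        out[val < model$t0_window[1] | val > model$t0_window[2]] <- -Inf
        out
      } else {
        k <- match(nm, shp_names)
        ltnorm(val, hyper_mu[k], hyper_tau[k])
      }
    }

    n_iter <- mcmc$n_warmup + mcmc$n_samples
    for (iter in seq_len(n_iter)) {
      adapting <- iter <= mcmc$n_warmup
      gam <- if (adapting) min(0.5, 2 / sqrt(iter)) else 0

      ## --- 1. AR(1) path, checkerboard blocks vectorised over provinces
      ## and years of one parity
      for (ps in parity_sets) {
        ts <- ps$ts
        K <- length(ts)
        lp_cur <- logphi[, ts, drop = FALSE]
        prop <- lp_cur + sc_phi[, ts, drop = FALSE] *
          matrix(rnorm(P * K), P, K)
        ## backward prior term: stationary for t = 1, transition otherwise
        mean_prev <- matrix(0, P, K)
        sd_prev <- matrix(sd_stat, P, K)
        if (any(ps$has_prev)) {
          mean_prev[, ps$has_prev] <-
            rho * logphi[, ts[ps$has_prev] - 1L]
          sd_prev[, ps$has_prev] <- sig
        }
        dlp <- dnorm(prop, mean_prev, sd_prev, log = TRUE) -
          dnorm(lp_cur, mean_prev, sd_prev, log = TRUE)
        ## forward prior term for sites with a successor
        if (any(ps$has_next)) {
          nx <- logphi[, ts[ps$has_next] + 1L, drop = FALSE]
          dlp[, ps$has_next] <- dlp[, ps$has_next] +
            dnorm(nx, rho * prop[, ps$has_next, drop = FALSE], sig,
                  log = TRUE) -
            dnorm(nx, rho * lp_cur[, ps$has_next, drop = FALSE], sig,
                  log = TRUE)
        }
        rows <- ps$rows
        if (length(rows) > 0L) {
          cell <- cbind(p_idx[rows], ps$site)
          th_cur <- b * exp(lp_cur[cell]) + delta[p_idx[rows]] *
            alpha_obs[rows]
          th_prop <- b * exp(prop[cell]) + delta[p_idx[rows]] *
            alpha_obs[rows]
          dll <- dnorm(logr[rows], log(th_prop), sigma[rows],
                       log = TRUE) -
            dnorm(logr[rows], log(th_cur), sigma[rows], log = TRUE)
          flat <- (ps$site - 1L) * P + p_idx[rows]
          agg <- rowsum(dll, flat)
          dlp[as.integer(rownames(agg))] <- dlp[as.integer(
            rownames(agg))] + agg
        }
        acc <- matrix(log(runif(P * K)), P, K) < dlp
        lp_cur[acc] <- prop[acc]
        logphi[, ts] <- lp_cur
        if (adapting) {
          sc_phi[, ts] <- sc_phi[, ts, drop = FALSE] *
            exp(gam * (acc - 0.44))
        }
        acc_tot["phi"] <- acc_tot["phi"] + sum(acc)
        acc_n["phi"] <- acc_n["phi"] + P * K
      }
      ## --- 1b. whole-path refresh: preconditioned Crank-Nicolson move,
      ## which leaves the Gaussian AR(1) prior invariant, so acceptance
      ## depends on the likelihood alone; this moves the level of the
      ## path, which single-site updates explore slowly.
      z <- matrix(0, P, T)
      z[, 1] <- rnorm(P, 0, sd_stat)
      for (t in seq_len(T)[-1]) z[, t] <- rho * z[, t - 1] + sig * rnorm(P)
      prop_lp <- sqrt(1 - beta_pcn^2) * logphi + beta_pcn * z
      dll <- numeric(P)
      if (n_obs > 0L) {
        th_cur <- b * exp(logphi[cbind(p_idx, t_idx)]) +
          delta[p_idx] * alpha_obs
        th_prop <- b * exp(prop_lp[cbind(p_idx, t_idx)]) +
          delta[p_idx] * alpha_obs
        dll <- sum_by_province(
          dnorm(logr, log(th_prop), sigma, log = TRUE) -
            dnorm(logr, log(th_cur), sigma, log = TRUE), p_idx, P)
      }
      acc <- log(runif(P)) < dll
      logphi[acc, ] <- prop_lp[acc, , drop = FALSE]
      if (adapting) {
        beta_pcn <- pmin(0.995, pmax(0.01,
          beta_pcn * exp(gam * ((acc) - 0.3))))
      }
      acc_tot["phi"] <- acc_tot["phi"] + sum(acc)
      acc_n["phi"] <- acc_n["phi"] + P

      phi_obs <- exp(logphi[cbind(p_idx, t_idx)])

      ## --- 2. trapezoid shape parameters, random walk per province;
      ## several sweeps per iteration since each is cheap relative to the
      ## path update and the shapes mix slowest under sharp likelihoods
      for (sweep in 1:3) for (nm in c("t0", shp_names)) {
        cur <- if (nm == "t0") t0 else shp[[nm]]
        prop <- cur + sc_shape[[nm]] * rnorm(P)
        ok <- if (nm == "t0") {
          prop >= model$t0_window[1] & prop <= model$t0_window[2]
        } else if (nm == "len_stagnation" || nm == "max_inflation") {
          prop >= 0
        } else {
          prop > 0
        }
        dlp <- shape_prior(nm, prop) - shape_prior(nm, cur)
        dlp[!ok] <- -Inf
        if (n_obs > 0L && any(delta == 1)) {
          pv <- list(t0 = t0, len_increase = shp$len_increase,
                     len_stagnation = shp$len_stagnation,
                     len_decrease = shp$len_decrease,
                     max_inflation = shp$max_inflation)
          pv[[nm]] <- prop
          alpha_prop <- alpha_tz(t_mid, pv$t0[p_idx],
                                 pv$len_increase[p_idx],
                                 pv$len_stagnation[p_idx],
                                 pv$len_decrease[p_idx],
                                 pv$max_inflation[p_idx])
          th_cur <- b * phi_obs + delta[p_idx] * alpha_obs
          th_prop <- b * phi_obs + delta[p_idx] * alpha_prop
          dll <- dnorm(logr, log(th_prop), sigma, log = TRUE) -
            dnorm(logr, log(th_cur), sigma, log = TRUE)
          dlp <- dlp + sum_by_province(dll, p_idx, P)
        }
        acc <- log(runif(P)) < dlp
        if (nm == "t0") t0[acc] <- prop[acc] else shp[[nm]][acc] <- prop[acc]
        if (any(acc)) {
          rows <- unlist(obs_by_p[acc], use.names = FALSE)
          if (length(rows) > 0L) {
            alpha_obs[rows] <- alpha_tz(
              t_mid[rows], t0[p_idx[rows]], shp$len_increase[p_idx[rows]],
              shp$len_stagnation[p_idx[rows]],
              shp$len_decrease[p_idx[rows]],
              shp$max_inflation[p_idx[rows]])
          }
        }
        if (adapting) {
          sc_shape[[nm]] <- sc_shape[[nm]] * exp(gam * ((acc) - 0.44))
        }
        acc_tot["shape"] <- acc_tot["shape"] + sum(acc)
        acc_n["shape"] <- acc_n["shape"] + P
      }

      ## --- 2b. joint shape refresh: independence proposal from the
      ## conditional prior (given current hypers), accepted on the
      ## likelihood ratio alone.  For delta = 0 provinces the likelihood
      ## is unchanged, so their shapes decorrelate immediately — the key
      ## to mixing across the spike-and-slab indicator.
      {
        rtnorm_vec <- function(mu, tau, lower = 0) {
          x <- rnorm(P, mu, tau)
          for (tries in 1:50) {
            bad_i <- which(!(x > lower))
            if (length(bad_i) == 0L) break
            x[bad_i] <- rnorm(length(bad_i), mu, tau)
          }
          x
        }
        prop_t0 <- loc + model$t0_scale * stats::rt(P, df = 3)
        prop_shp <- list(
          len_increase = rtnorm_vec(hyper_mu[1], hyper_tau[1]),
          len_stagnation = rtnorm_vec(hyper_mu[2], hyper_tau[2]),
          len_decrease = rtnorm_vec(hyper_mu[3], hyper_tau[3]),
          max_inflation = rtnorm_vec(hyper_mu[4], hyper_tau[4]))
        ok <- prop_t0 >= model$t0_window[1] &
          prop_t0 <= model$t0_window[2] &
          prop_shp$len_increase > 0 & prop_shp$len_stagnation > 0 &
          prop_shp$len_decrease > 0 & prop_shp$max_inflation > 0
        dll <- numeric(P)
        if (n_obs > 0L && any(delta == 1)) {
          alpha_prop <- alpha_tz(t_mid, prop_t0[p_idx],
                                 prop_shp$len_increase[p_idx],
                                 prop_shp$len_stagnation[p_idx],
                                 prop_shp$len_decrease[p_idx],
                                 prop_shp$max_inflation[p_idx])
          th_cur <- b * phi_obs + delta[p_idx] * alpha_obs
          th_prop <- b * phi_obs + delta[p_idx] * alpha_prop
          dll <- sum_by_province(
            dnorm(logr, log(th_prop), sigma, log = TRUE) -
              dnorm(logr, log(th_cur), sigma, log = TRUE), p_idx, P)
        }
        dll[!ok] <- -Inf
        acc <- log(runif(P)) < dll
        if (any(acc)) {
          t0[acc] <- prop_t0[acc]
          for (nm in shp_names) shp[[nm]][acc] <- prop_shp[[nm]][acc]
          rows <- unlist(obs_by_p[acc], use.names = FALSE)
          if (length(rows) > 0L) {
            alpha_obs[rows] <- alpha_tz(
              t_mid[rows], t0[p_idx[rows]], shp$len_increase[p_idx[rows]],
              shp$len_stagnation[p_idx[rows]],
              shp$len_decrease[p_idx[rows]],
              shp$max_inflation[p_idx[rows]])
          }
        }
        acc_tot["shape"] <- acc_tot["shape"] + sum(acc)
        acc_n["shape"] <- acc_n["shape"] + P
      }

      ## --- 3. exact two-point Gibbs for the inflation indicator
      if (n_obs > 0L) {
        th1 <- b * phi_obs + alpha_obs
        th0 <- b * phi_obs
        ll1 <- sum_by_province(dnorm(logr, log(th1), sigma, log = TRUE),
                               p_idx, P)
        ll0 <- sum_by_province(dnorm(logr, log(th0), sigma, log = TRUE),
                               p_idx, P)
        log_odds <- log(prob_delta) - log1p(-prob_delta) + ll1 - ll0
      } else {
        log_odds <- log(prob_delta) - log1p(-prob_delta)
      }
      delta <- as.numeric(runif(P) < plogis(log_odds))

      ## --- 4. conjugate Beta step for the indicator means (U(0,1) prior)
      prob_delta <- rbeta(P, 1 + delta, 2 - delta)

      ## --- 5. shape hyperparameters (several cheap sweeps, as above)
      for (sweep in 1:3) for (k in seq_along(shp_names)) {
        v <- shp[[shp_names[k]]]
        ## across-province mean: propose from the conjugate normal that
        ## ignores the truncation normaliser; the MH correction is the
        ## normaliser ratio only, so acceptance is near 1.
        s2_post <- 1 / (1 / s0[k]^2 + P / hyper_tau[k]^2)
        m_post <- s2_post * (m0[k] / s0[k]^2 + sum(v) / hyper_tau[k]^2)
        prop_mu <- rnorm(1, m_post, sqrt(s2_post))
        dlp <- -P * (pnorm(prop_mu / hyper_tau[k], log.p = TRUE) -
                       pnorm(hyper_mu[k] / hyper_tau[k], log.p = TRUE))
        acc_mu <- log(runif(1)) < dlp
        if (acc_mu) {
          hyper_mu[k] <- prop_mu
          acc_tot["hyper"] <- acc_tot["hyper"] + 1
        }
        acc_n["hyper"] <- acc_n["hyper"] + 1
        ## across-province sd
        prop_tau <- hyper_tau[k] + sc_hyper_tau[k] * rnorm(1)
        if (prop_tau > 0) {
          dlp <- lhalfnorm(prop_tau, tau_scale[k]) -
            lhalfnorm(hyper_tau[k], tau_scale[k]) +
            sum(ltnorm(v, hyper_mu[k], prop_tau) -
                  ltnorm(v, hyper_mu[k], hyper_tau[k]))
          acc1 <- log(runif(1)) < dlp
          if (acc1) {
            hyper_tau[k] <- prop_tau
            acc_tot["hyper"] <- acc_tot["hyper"] + 1
          }
          if (adapting) {
            sc_hyper_tau[k] <- sc_hyper_tau[k] * exp(gam * (acc1 - 0.44))
          }
        } else if (adapting) {
          sc_hyper_tau[k] <- sc_hyper_tau[k] * exp(gam * (0 - 0.44))
        }
        acc_n["hyper"] <- acc_n["hyper"] + 1
      }

      ## --- store
      if (!adapting) {
        it_post <- iter - mcmc$n_warmup
        if (it_post %% mcmc$thin == 0L) {
          row_at <- row_at + 1L
          store$phi[row_at, , ] <- exp(logphi)
          store$delta[row_at, ] <- delta
          store$prob_delta[row_at, ] <- prob_delta
          store$t0[row_at, ] <- t0
          store$len_increase[row_at, ] <- shp$len_increase
          store$len_stagnation[row_at, ] <- shp$len_stagnation
          store$len_decrease[row_at, ] <- shp$len_decrease
          store$max_inflation[row_at, ] <- shp$max_inflation
          store$hyper_mu[row_at, ] <- hyper_mu
          store$hyper_tau[row_at, ] <- hyper_tau
          state <- list(phi = exp(logphi), delta = delta,
                        prob_delta = prob_delta, t0 = t0,
                        len_increase = shp$len_increase,
                        len_stagnation = shp$len_stagnation,
                        len_decrease = shp$len_decrease,
                        max_inflation = shp$max_inflation,
                        hyper_mu = hyper_mu, hyper_tau = hyper_tau)
          store$lp[row_at] <- .log_posterior_fast(
            state, b, rho, sig, sd_stat, logr, sigma, p_idx, t_idx, t_mid,
            loc, model, m0, s0, tau_scale, shp_names)
        }
      }
    }
  }

  ## monitored scalars for the diagnostics table
  mon <- list(lp = store$lp)
  for (p in seq_len(P)) {
    mon[[paste0("t0[", provinces[p], "]")]] <- store$t0[, p]
    mon[[paste0("max_inflation[", provinces[p], "]")]] <-
      store$max_inflation[, p]
    mon[[paste0("mean_log_phi[", provinces[p], "]")]] <-
      rowMeans(matrix(log(store$phi[, p, , drop = FALSE]),
                      nrow = n_store))
  }
  for (k in seq_along(shp_names)) {
    mon[[paste0("hyper_mu[", shp_names[k], "]")]] <- store$hyper_mu[, k]
  }
  diag_tab <- compute_diagnostics(mon, chain_id)

  fit <- structure(list(
    draws = store, chain_id = chain_id, provinces = provinces,
    years = years, model = model, mcmc = mcmc, data = data, tfr = tfr,
    start_year_location = loc,
    diagnostics = diag_tab,
    acceptance = acc_tot / pmax(acc_n, 1)),
    class = "srb_fit")

  bad <- diag_tab$rhat[!is.na(diag_tab$rhat)]
  if (any(bad > mcmc$rhat_threshold)) {
    warning("MCMC convergence suspect: ",
            sum(bad > mcmc$rhat_threshold), " monitored scalar(s) with ",
            "split R-hat > ", mcmc$rhat_threshold,
            " (max = ", round(max(bad), 3), "); inspect fit$diagnostics",
            call. = FALSE)
    fit$converged <- FALSE
  } else {
    fit$converged <- TRUE
  }
  ess_ok <- diag_tab$ess[!is.na(diag_tab$ess)]
  fit$low_ess <- any(ess_ok < mcmc$ess_threshold)
  if (fit$low_ess) {
    message("note: ", sum(ess_ok < mcmc$ess_threshold),
            " monitored scalar(s) with ESS below ", mcmc$ess_threshold,
            "; consider longer chains")
  }
  fit
}

## Fast full log posterior from precomputed bookkeeping (same terms as
## log_posterior(); the test suite checks the two agree).
.log_posterior_fast <- function(state, b, rho, sig, sd_stat, logr, sigma,
                                p_idx, t_idx, t_mid, loc, model,
                                m0, s0, tau_scale, shp_names) {
  P <- nrow(state$phi)
  lp <- 0
  if (length(logr) > 0L) {
    alpha_obs <- alpha_tz(t_mid, state$t0[p_idx],
                          state$len_increase[p_idx],
                          state$len_stagnation[p_idx],
                          state$len_decrease[p_idx],
                          state$max_inflation[p_idx])
    theta <- b * state$phi[cbind(p_idx, t_idx)] +
      state$delta[p_idx] * alpha_obs
    lp <- lp + sum(dnorm(logr, log(theta), sigma, log = TRUE))
  }
  lphi <- log(state$phi)
  lp <- lp + sum(dnorm(lphi[, 1], 0, sd_stat, log = TRUE))
  if (ncol(lphi) > 1L) {
    lp <- lp + sum(dnorm(lphi[, -1], rho * lphi[, -ncol(lphi)], sig,
                         log = TRUE))
  }
  for (k in seq_along(shp_names)) {
    lp <- lp + sum(ltnorm(state[[shp_names[k]]], state$hyper_mu[k],
                          state$hyper_tau[k])) +
      dnorm(state$hyper_mu[k], m0[k], s0[k], log = TRUE) +
      lhalfnorm(state$hyper_tau[k], tau_scale[k])
  }
  lp <- lp + sum(start_year_logprior(state$t0, loc, model$t0_scale)) +
    sum(stats::dbinom(state$delta, 1, state$prob_delta, log = TRUE))
  lp
}

#' Posterior probability of SRB inflation
#'
#' The share of posterior draws in which a province's inflation indicator
#' delta equals 1 — the model's probability that the province has
#' undergone (or will undergo) a sex-ratio transition.
#'
#' @param fit an `srb_fit`.
#' @param province optional single province label; default all.
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
inflation_probability <- function(fit, province = NULL) {
  stopifnot(inherits(fit, "srb_fit"))
  pr <- colMeans(fit$draws$delta)
  if (!is.null(province)) {
    if (!province %in% fit$provinces) {
      stop("unknown province: ", province, call. = FALSE)
    }
    pr <- pr[province]
  }
  pr
}

## Posterior draws of Theta over a set of calendar years as an
## [n_draws, P, length(years)] array.  Years beyond the stored phi grid are
## not handled here (see project_srb()).
theta_draws <- function(fit, years = fit$years) {
  stopifnot(all(years %in% fit$years))
  d <- fit$draws
  nd <- nrow(d$delta)
  P <- length(fit$provinces)
  t_sel <- match(years, fit$years)
  out <- array(NA_real_, c(nd, P, length(years)),
               dimnames = list(NULL, fit$provinces, years))
  tmat <- matrix(rep(years, each = nd), nd, length(years))
  for (p in seq_len(P)) {
    A <- alpha_tz(tmat, d$t0[, p], d$len_increase[, p],
                  d$len_stagnation[, p], d$len_decrease[, p],
                  d$max_inflation[, p])
    out[, p, ] <- fit$model$b * d$phi[, p, t_sel] + d$delta[, p] * A
  }
  out
}

#' Posterior summary of the SRB by province and year
#'
#' Quantiles of the posterior of Theta for each province-year on the
#' estimation grid.
#'
#' @param fit an `srb_fit`.
#' @param years subset of the estimation grid (default: all).
#' @param quantiles probabilities to report; default 2.5%, median, 97.5%.
#' @return data frame `province`, `year`, `quantile_<q>`... of class
#'   `srb_summary`.
#' @export
summarize_srb <- function(fit, years = NULL,
                          quantiles = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "srb_fit"))
  if (is.null(years)) years <- fit$years
  th <- theta_draws(fit, years)
  qn <- paste0("quantile_", quantiles)
  rows <- list()
  for (p in seq_along(fit$provinces)) {
    m <- matrix(th[, p, , drop = FALSE], nrow = dim(th)[1])
    q <- apply(m, 2, quantile, probs = quantiles, names = FALSE)
    if (is.null(dim(q))) q <- matrix(q, nrow = length(quantiles))
    block <- data.frame(province = fit$provinces[p], year = years,
                        stringsAsFactors = FALSE)
    for (i in seq_along(quantiles)) block[[qn[i]]] <- q[i, ]
    rows[[p]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("srb_summary", "data.frame")
  out
}

#' Start year of the sex-ratio transition, summarised
#'
#' Posterior median and 95% interval of the transition start year,
#' conditional on inflation occurring (draws with delta = 1), plus the TFR
#' at the median start year looked up from the fitted TFR input.  Start
#' years are reported as integer calendar years; ties in the median break
#' to the earlier year (lower order statistic).
#'
#' @param fit an `srb_fit`.
#' @param province a province label.
#' @return list with `defined`, `median`, `lower`, `upper`, `tfr_at_median`,
#'   `n_draws` (number of delta = 1 draws).  If no draw has delta = 1 the
#'   result is flagged `defined = FALSE` (with a warning) rather than
#'   silently returning a year.
#' @export
start_year_summary <- function(fit, province) {
  stopifnot(inherits(fit, "srb_fit"))
  if (!province %in% fit$provinces) {
    stop("unknown province: ", province, call. = FALSE)
  }
  sel <- fit$draws$delta[, province] == 1
  if (!any(sel)) {
    warning("no posterior draw has delta = 1 for ", province,
            "; start year undefined", call. = FALSE)
    return(list(defined = FALSE, median = NA_integer_, lower = NA_integer_,
                upper = NA_integer_, tfr_at_median = NA_real_,
                n_draws = 0L))
  }
  t0 <- round(fit$draws$t0[sel, province])
  qs <- quantile(t0, c(0.025, 0.5, 0.975), type = 1, names = FALSE)
  tp <- fit$tfr[fit$tfr$province == province, , drop = FALSE]
  tfr_at <- if (qs[2] %in% tp$year) tp$tfr[match(qs[2], tp$year)] else
    NA_real_
  list(defined = TRUE, median = as.integer(qs[2]),
       lower = as.integer(qs[1]), upper = as.integer(qs[3]),
       tfr_at_median = tfr_at, n_draws = sum(sel))
}

#' @export
print.srb_fit <- function(x, ...) {
  cat("Hierarchical SRB model fit\n")
  cat("  provinces:", length(x$provinces), " years:",
      min(x$years), "-", max(x$years), "\n")
  cat("  draws:", nrow(x$draws$delta), "(", x$mcmc$n_chains, "chain(s))",
      " seed:", x$mcmc$seed, "\n")
  cat("  inflation probabilities:\n")
  print(round(inflation_probability(x), 3))
  rh <- x$diagnostics$rhat
  cat("  max split R-hat:", round(max(rh, na.rm = TRUE), 3),
      " min ESS:", round(min(x$diagnostics$ess, na.rm = TRUE)), "\n")
  invisible(x)
}
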