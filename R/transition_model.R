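#' Trapezoid shape of a sex-ratio transition
#'
#' A sex-ratio transition is parameterised by its start year, the lengths of
#' its three stages — increase, stagnation, and convergence back to the
#' national baseline — and the maximum level of SRB inflation reached.
#'
#' @param start_year calendar year the inflation begins.
#' @param len_increase,len_stagnation,len_decrease stage lengths in years;
#'   increase and decrease must be > 0, stagnation >= 0.
#' @param max_inflation maximum SRB inflation (dimensionless, >= 0).
#' @return a list of class `transition_shape`.
#' @export
transition_shape <- function(start_year, len_increase, len_stagnation,
                             len_decrease, max_inflation) {
  stopifnot(len_increase > 0, len_stagnation >= 0, len_decrease > 0,
            max_inflation >= 0)
  structure(
    list(start_year = start_year, len_increase = len_increase,
         len_stagnation = len_stagnation, len_decrease = len_decrease,
         max_inflation = max_inflation),
    class = "transition_shape")
}

## Fully vectorised trapezoid: t and all shape parameters may be vectors of
## equal (or recyclable) length.  Workhorse behind alpha_trapezoid() and the
## sampler, which evaluates per-observation shapes in bulk.
alpha_tz <- function(t, t0, l1, l2, l3, xi) {
  ## piecewise-linear trapezoid as the clamped minimum of the rising and
  ## falling ramps (subset assignment, not pmin/ifelse: hot sampler path)
  u <- t - t0
  a <- u / l1
  r2 <- (l1 + l2 + l3 - u) / l3
  sel <- r2 < a
  a[sel] <- r2[sel]
  a[a < 0] <- 0
  a[a > 1] <- 1
  xi * a
}

#' Trapezoid inflation function
#'
#' Evaluates the SRB inflation alpha at time `t` for a given transition
#' shape: zero up to the start year, linear rise to the maximum over the
#' increase stage, constant over the stagnation stage, linear fall back to
#' zero over the decrease stage, and zero afterwards.  Continuous and
#' non-negative everywhere.
#'
#' @param t calendar year (vectorised).
#' @param shape a [transition_shape()].
#' @return inflation value(s) in `[0, max_inflation]`.
#' @export
alpha_trapezoid <- function(t, shape) {
  stopifnot(inherits(shape, "transition_shape"))
  alpha_tz(t, shape$start_year, shape$len_increase, shape$len_stagnation,
           shape$len_decrease, shape$max_inflation)
}

#' Expected sex ratio at birth
#'
#' Assembles the model's SRB for one province-year: the national baseline
#' `b` modulated by the natural-fluctuation factor `phi`, plus the
#' transition inflation `alpha` if the province's inflation indicator
#' `delta` is on:
#' `Theta = b * phi + delta * alpha`.
#'
#' @param b national SRB baseline ratio (default 1.049).
#' @param phi natural-fluctuation multiplier (> 0, approximately 1).
#' @param delta binary inflation indicator (0 or 1).
#' @param alpha trapezoid inflation value (>= 0).
#' @return the SRB Theta (> 0); vectorised.
#' @export
srb_mean <- function(b = 1.049, phi = 1, delta = 0, alpha = 0) {
  stopifnot(all(phi > 0), all(alpha >= 0))
  b * phi + delta * alpha
}

#' Log density of the AR(1) natural-fluctuation path
#'
#' The fluctuation factor phi follows a first-order autoregressive process
#' on the log scale: log(phi_1) from the stationary distribution
#' N(0, sigma^2 / (1 - rho^2)) and
#' log(phi_t) | log(phi_{t-1}) ~ N(rho * log(phi_{t-1}), sigma^2).
#'
#' @param phi positive vector, the path (phi_1, ..., phi_T).
#' @param rho autocorrelation, in (0, 1).
#' @param sigma innovation standard deviation on the log scale (> 0).
#' @return the joint log density.
#' @export
ar1_logdensity <- function(phi, rho, sigma) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)", call. = FALSE)
  stopifnot(sigma > 0, all(phi > 0))
  lp <- log(phi)
  T <- length(lp)
  out <- dnorm(lp[1], 0, sigma / sqrt(1 - rho^2), log = TRUE)
  if (T > 1L) {
    out <- out + sum(dnorm(lp[-1], rho * lp[-T], sigma, log = TRUE))
  }
  unname(out)
}

#' Locate the start-year prior from fertility decline
#'
#' The fertility-squeeze mechanism ties the onset of sex selection to
#' fertility decline: the prior for a province's transition start year is
#' centred on the first year its total fertility rate falls to or below the
#' reference level `f_star`.  If the TFR never reaches `f_star` the last
#' year of the series is returned with a warning.
#'
#' @param tfr data frame with columns `year` and `tfr` for one province,
#'   sorted by year.
#' @param f_star TFR reference level (children per woman, > 0).
#' @return a calendar year.
#' @export
start_year_location <- function(tfr, f_star) {
  stopifnot(f_star > 0, all(tfr$tfr > 0))
  idx <- which(tfr$tfr <= f_star)
  if (length(idx) == 0L) {
    warning("TFR never falls to f_star = ", f_star,
            "; using the last year of the series", call. = FALSE)
    return(tfr$year[nrow(tfr)])
  }
  tfr$year[idx[1]]
}

#' Student-t log prior for the transition start year
#'
#' The start year follows a Student-t distribution with three degrees of
#' freedom, centred at the TFR-derived location: the heavy tails let the
#' model accommodate provinces whose fertility path is an outlier relative
#' to the national fertility-squeeze experience.
#'
#' @param t0 start year (vectorised).
#' @param location centre of the prior (from [start_year_location()]).
#' @param scale prior scale in years (> 0).
#' @param df degrees of freedom; fixed at 3 unless `allow_other_df = TRUE`.
#' @param allow_other_df set `TRUE` to override the df = 3 convention.
#' @return log density value(s).
#' @export
start_year_logprior <- function(t0, location, scale, df = 3,
                                allow_other_df = FALSE) {
  stopifnot(scale > 0)
  if (df != 3 && !allow_other_df) {
    stop("start-year prior uses df = 3; set allow_other_df = TRUE to ",
         "override", call. = FALSE)
  }
  dt((t0 - location) / scale, df = df, log = TRUE) - log(scale)
}

#' Observation log likelihood
#'
#' The observed ratio r is log-normally distributed around the model SRB:
#' `log(r) | Theta ~ N(log(Theta), sigma^2)`, with sigma the observation's
#' precomputed (jackknife) sampling error.
#'
#' @param r observed SRB (> 0).
#' @param sigma log-scale sampling error (> 0).
#' @param theta model SRB (> 0).
#' @return log density value(s); vectorised.
#' @export
obs_loglik <- function(r, sigma, theta) {
  if (any(!(sigma > 0))) {
    stop("observations must carry a positive sampling error", call. = FALSE)
  }
  stopifnot(all(r > 0), all(theta > 0))
  dnorm(log(r), log(theta), sigma, log = TRUE)
}

#' Model configuration
#'
#' Collects the fixed constants and prior settings of the hierarchical SRB
#' model.  The AR(1) parameters and the baseline are fixed (not sampled):
#' national-level information is imported rather than re-estimated, because
#' the provincial birth samples are too small to identify it.
#'
#' @param b national SRB baseline ratio; 1.049 male per female birth.
#' @param rho AR(1) autocorrelation of log(phi), in (0, 1).
#' @param sigma_ar AR(1) innovation sd on the log scale.
#' @param years integer calendar-year estimation grid.
#' @param f_star TFR level (children/woman) that locates the start-year
#'   prior (the fertility squeeze).
#' @param t0_scale scale (years) of the Student-t(3) start-year prior.
#' @param t0_window allowed window `c(min, max)` for start years; draws are
#'   restricted to it.
#' @param shape_hyper hyperprior settings for the hierarchical trapezoid
#'   shape distributions: a list with elements `len_increase`,
#'   `len_stagnation`, `len_decrease`, `max_inflation`, each a list
#'   `list(m0, s0, tau_scale)` — normal prior N(m0, s0^2) on the
#'   across-province mean and half-normal(tau_scale) prior on the
#'   across-province sd.  Province-level shapes follow truncated-normal
#'   (>= 0) distributions under these hyperparameters.  Defaults centre the
#'   total transition length at 36 years (13 + 10 + 13) and the maximum
#'   inflation at 0.05.
#' @param midpoint_likelihood if `TRUE` (default) a multi-year observation
#'   is evaluated at its midpoint year; if `FALSE`, Theta is averaged over
#'   the period.
#' @return a list of class `srb_model_config`.
#' @export
model_config <- function(b = 1.049,
                         rho = 0.9,
                         sigma_ar = 0.004,
                         years = 1976:2016,
                         f_star = 3.0,
                         t0_scale = 10,
                         t0_window = c(1970, 2049),
                         shape_hyper = list(
                           len_increase   = list(m0 = 13, s0 = 3, tau_scale = 5),
                           len_stagnation = list(m0 = 10, s0 = 3, tau_scale = 5),
                           len_decrease   = list(m0 = 13, s0 = 3, tau_scale = 5),
                           max_inflation  = list(m0 = 0.05, s0 = 0.02,
                                                 tau_scale = 0.02)),
                         midpoint_likelihood = TRUE) {
  stopifnot(b > 0, rho > 0, rho < 1, sigma_ar > 0, f_star > 0,
            t0_scale > 0, length(t0_window) == 2L,
            t0_window[1] < t0_window[2])
  needed <- c("len_increase", "len_stagnation", "len_decrease",
              "max_inflation")
  stopifnot(all(needed %in% names(shape_hyper)))
  for (nm in needed) {
    stopifnot(shape_hyper[[nm]]$s0 > 0, shape_hyper[[nm]]$tau_scale > 0)
  }
  structure(
    list(b = b, rho = rho, sigma_ar = sigma_ar, years = as.integer(years),
         f_star = f_star, t0_scale = t0_scale, t0_window = t0_window,
         shape_hyper = shape_hyper,
         midpoint_likelihood = midpoint_likelihood),
    class = "srb_model_config")
}

## log density of a normal truncated to (0, Inf); the normaliser
## Phi(mu/tau) must be kept because mu and tau are themselves sampled.
ltnorm <- function(x, mu, tau) {
  out <- dnorm(x, mu, tau, log = TRUE) - pnorm(mu / tau, log.p = TRUE)
  out[x < 0] <- -Inf
  out
}

## half-normal log density (x > 0, scale s)
lhalfnorm <- function(x, s) {
  out <- log(2) + dnorm(x, 0, s, log = TRUE)
  out[x <= 0] <- -Inf
  out
}

#' Full log posterior of the hierarchical SRB model
#'
#' Sums, for a complete parameter state: the observation log likelihood
#' ([obs_loglik()] at each observation's midpoint year), the AR(1) log
#' density of each province's phi path, the truncated-normal hierarchical
#' log priors of the trapezoid shape parameters, the Student-t(3) start-year
#' log prior (TFR-located), the Bernoulli log mass of the inflation
#' indicators, the Uniform(0,1) hyperprior of the indicator means (zero),
#' and the normal / half-normal hyperpriors of the shape hyperparameters.
#'
#' Primarily a reference implementation: the sampler updates the same terms
#' incrementally, and tests compare the two.
#'
#' @param state list with elements `phi` (provinces x years matrix, > 0),
#'   `delta` (binary vector), `prob_delta` (vector in (0,1)), `t0`, `len_increase`,
#'   `len_stagnation`, `len_decrease`, `max_inflation` (numeric vectors, one
#'   entry per province), `hyper_mu` and `hyper_tau` (named vectors over the
#'   four shape parameters).
#' @param data an `srb_obs` observation set.
#' @param tfr data frame `province`, `year`, `tfr` covering every province.
#' @param model a [model_config()].
#' @return a finite scalar for any state satisfying the invariants
#'   (`-Inf` if a hard constraint is violated).
#' @export
log_posterior <- function(state, data, tfr, model = model_config()) {
  provinces <- rownames(state$phi)
  if (is.null(provinces)) provinces <- as.character(seq_len(nrow(state$phi)))
  P <- length(provinces)
  years <- model$years
  shp_names <- c("len_increase", "len_stagnation", "len_decrease",
                 "max_inflation")

  ## hard support checks
  if (any(state$phi <= 0)) return(-Inf)
  if (any(state$t0 < model$t0_window[1] | state$t0 > model$t0_window[2])) {
    return(-Inf)
  }
  if (any(state$len_increase <= 0) || any(state$len_decrease <= 0) ||
      any(state$len_stagnation < 0) || any(state$max_inflation < 0)) {
    return(-Inf)
  }
  if (any(state$hyper_tau[shp_names] <= 0)) return(-Inf)

  df <- as.data.frame(data)
  p_idx <- match(df$province, provinces)
  if (any(is.na(p_idx))) {
    stop("observation province without a model state: ",
         paste(unique(df$province[is.na(p_idx)]), collapse = ", "),
         call. = FALSE)
  }
  t_mid <- period_midpoint_year(df$period_start, df$period_end)
  t_idx <- match(t_mid, years)
  if (any(is.na(t_idx))) {
    stop("observation midpoint year outside the model grid", call. = FALSE)
  }

  alpha_obs <- alpha_tz(t_mid, state$t0[p_idx], state$len_increase[p_idx],
                        state$len_stagnation[p_idx],
                        state$len_decrease[p_idx],
                        state$max_inflation[p_idx])
  theta <- model$b * state$phi[cbind(p_idx, t_idx)] +
    state$delta[p_idx] * alpha_obs
  ll <- sum(obs_loglik(df$srb, df$log_se, theta))

  lp_ar <- sum(vapply(seq_len(P), function(p) {
    ar1_logdensity(state$phi[p, ], model$rho, model$sigma_ar)
  }, numeric(1)))

  lp_shapes <- 0
  for (nm in shp_names) {
    lp_shapes <- lp_shapes +
      sum(ltnorm(state[[nm]], state$hyper_mu[nm], state$hyper_tau[nm]))
  }

  loc <- vapply(provinces, function(p) {
    start_year_location(tfr[tfr$province == p, , drop = FALSE],
                        model$f_star)
  }, numeric(1))
  lp_t0 <- sum(start_year_logprior(state$t0, loc, model$t0_scale))

  lp_delta <- sum(stats::dbinom(state$delta, 1, state$prob_delta,
                                log = TRUE))

  lp_hyper <- 0
  for (nm in shp_names) {
    h <- model$shape_hyper[[nm]]
    lp_hyper <- lp_hyper +
      dnorm(state$hyper_mu[nm], h$m0, h$s0, log = TRUE) +
      lhalfnorm(state$hyper_tau[nm], h$tau_scale)
  }

  total <- unname(ll + lp_ar + lp_shapes + lp_t0 + lp_delta + lp_hyper)
  if (!is.finite(total)) {
    parts <- c(likelihood = ll, ar1 = lp_ar, shapes = lp_shapes,
               start_year = lp_t0, delta = lp_delta, hyper = lp_hyper)
    bad <- names(parts)[!is.finite(parts)]
    stop("non-finite log-posterior component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  total
}
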