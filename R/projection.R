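#' Probabilistic projection of the SRB
#'
#' Extends every posterior draw beyond the estimation period: the natural
#' fluctuation phi is propagated forward by simulating the AR(1) recursion
#' on the log scale, and the trapezoid inflation alpha is evaluated through
#' the horizon from each draw's shape parameters — including draws whose
#' start year lies in the future, which is how "the SRB will inflate with a
#' probability" is realised.  Theta is assembled per draw and summarised by
#' quantiles per province-year.  Estimation-period summaries are untouched:
#' projection appends, never rewrites.
#'
#' TFR enters the model only through the start-year prior location, which is
#' resolved at fit time; supply a TFR series covering the horizon to
#' [fit_srb_mcmc()] if future fertility should inform future start years.
#'
#' @param fit an `srb_fit`.
#' @param horizon_year last projected calendar year (default 2050); must
#'   be after the estimation grid.
#' @param seed RNG seed for the forward AR(1) simulation.
#' @param quantiles probabilities to report.
#' @param convergence_tol half-width of the band around the baseline `b`
#'   within which a median trajectory counts as converged (default 0.002).
#' @return an object of class `srb_projection`: `summary` (data frame
#'   `province`, `year`, `quantile_<q>`...), `by_province` (data frame with
#'   the year of maximum projected median, the median SRB in that year, and
#'   the first year the median is back within `convergence_tol` of the
#'   baseline), the projected draws, years, and seed.
#' @export
project_srb <- function(fit, horizon_year = 2050, seed = 1L,
                        quantiles = c(0.025, 0.5, 0.975),
                        convergence_tol = 0.002) {
  stopifnot(inherits(fit, "srb_fit"))
  last_est <- max(fit$years)
  if (horizon_year <= last_est) {
    stop("horizon_year must be after the last estimation year (",
         last_est, ")", call. = FALSE)
  }
  years_proj <- (last_est + 1):horizon_year
  Tp <- length(years_proj)
  d <- fit$draws
  nd <- nrow(d$delta)
  P <- length(fit$provinces)
  rho <- fit$model$rho
  sig <- fit$model$sigma_ar
  b <- fit$model$b

  set.seed(seed)
  ## forward AR(1): all draws and provinces advanced together
  lphi <- log(d$phi[, , length(fit$years)])  # [nd, P] at the last data year
  if (is.null(dim(lphi))) lphi <- matrix(lphi, nd, P)
  theta <- array(NA_real_, c(nd, P, Tp),
                 dimnames = list(NULL, fit$provinces, years_proj))
  for (j in seq_len(Tp)) {
    lphi <- rho * lphi + sig * matrix(rnorm(nd * P), nd, P)
    yr <- years_proj[j]
    for (p in seq_len(P)) {
      A <- alpha_tz(yr, d$t0[, p], d$len_increase[, p],
                    d$len_stagnation[, p], d$len_decrease[, p],
                    d$max_inflation[, p])
      theta[, p, j] <- b * exp(lphi[, p]) + d$delta[, p] * A
    }
  }

  qn <- paste0("quantile_", quantiles)
  rows <- list()
  for (p in seq_len(P)) {
    m <- matrix(theta[, p, , drop = FALSE], nrow = nd)
    q <- apply(m, 2, quantile, probs = quantiles, names = FALSE)
    if (is.null(dim(q))) q <- matrix(q, nrow = length(quantiles))
    block <- data.frame(province = fit$provinces[p], year = years_proj,
                        stringsAsFactors = FALSE)
    for (i in seq_along(quantiles)) block[[qn[i]]] <- q[i, ]
    rows[[p]] <- block
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  med_col <- qn[which.min(abs(quantiles - 0.5))]
  by_prov <- do.call(rbind, lapply(seq_len(P), function(p) {
    med <- summary_df[summary_df$province == fit$provinces[p], med_col]
    imax <- which.max(med)  # ties break to the earliest year
    inband <- which(abs(med - b) < convergence_tol)
    data.frame(province = fit$provinces[p],
               max_year = years_proj[imax],
               max_median_srb = med[imax],
               convergence_year = if (length(inband) > 0L)
                 years_proj[inband[1]] else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_prov) <- NULL

  structure(list(summary = summary_df, by_province = by_prov,
                 theta = theta, years = years_proj, seed = seed,
                 baseline = b, convergence_tol = convergence_tol),
            class = "srb_projection")
}

#' Year of maximum projected SRB
#'
#' The year in which a province's projected median SRB reaches its maximum,
#' and the median SRB in that year.  Ties break to the earliest year.
#'
#' @param result an `srb_projection`.
#' @param province a province label.
#' @return list with `year` and `median_srb`.
#' @export
max_inflation_year <- function(result, province) {
  stopifnot(inherits(result, "srb_projection"))
  row <- result$by_province[result$by_province$province == province, ]
  if (nrow(row) == 0L) stop("unknown province: ", province, call. = FALSE)
  list(year = row$max_year, median_srb = row$max_median_srb)
}

#' Share of the sex-ratio transition covered by data
#'
#' For each posterior draw with delta = 1, the transition occupies the
#' interval from the start year to the end of the decrease stage.  This
#' reports, per province, the posterior median of the fraction of integer
#' years in that interval whose year is overlapped by at least one
#' observation period, together with the across-province averages of years
#' covered and total transition length — a measure of how much of the
#' projected transition is actually constrained by data.
#'
#' @param fit an `srb_fit`.
#' @param data observation set (default: the data the model was fit to).
#' @return list with `per_province` (data frame: province, median share,
#'   median years covered, median transition length), `avg_share`,
#'   `avg_years_covered`, `avg_transition_length` (averaged over provinces
#'   with any delta = 1 draw).
#' @export
transition_data_coverage <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "srb_fit"))
  df <- as.data.frame(data)
  d <- fit$draws
  per <- lapply(seq_along(fit$provinces), function(p) {
    prov <- fit$provinces[p]
    sel <- d$delta[, p] == 1
    if (!any(sel)) {
      return(data.frame(province = prov, share = NA_real_,
                        years_covered = NA_real_,
                        transition_length = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ps <- df$period_start[df$province == prov]
    pe <- df$period_end[df$province == prov]
    t0 <- d$t0[sel, p]
    len <- d$len_increase[sel, p] + d$len_stagnation[sel, p] +
      d$len_decrease[sel, p]
    covered <- vapply(seq_along(t0), function(i) {
      ## integer years in the half-open interval (t0, t0 + length], so a
      ## fully observed transition scores exactly 1
      lo <- floor(t0[i]) + 1
      hi <- floor(t0[i] + len[i])
      if (hi < lo || length(ps) == 0L) return(0)
      yrs <- seq(lo, hi)
      sum(vapply(yrs, function(y) any(ps <= y & pe >= y), logical(1)))
    }, numeric(1))
    data.frame(province = prov,
               share = median(covered / len),
               years_covered = median(covered),
               transition_length = median(len),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ok <- !is.na(per$share)
  list(per_province = per,
       avg_share = mean(per$share[ok]),
       avg_years_covered = mean(per$years_covered[ok]),
       avg_transition_length = mean(per$transition_length[ok]))
}
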