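## Column schema of the provincial SRB observation database.  One row per
## survey/census data point: reference period, sex-specific birth counts
## (possibly design-weighted, hence non-integer), the observed ratio r and
## its log-scale sampling error sigma.
srb_db_columns <- c(
  "province", "source", "period_start", "period_end",
  "male_births", "female_births", "srb", "log_se", "survey_year"
)

#' Construct a validated set of SRB observations
#'
#' Validates a data frame of province-level sex-ratio-at-birth observations
#' and attaches the `srb_obs` class.  Each row is one survey or census data
#' point: a reference period (`period_start`..`period_end`, inclusive
#' calendar years), sex-specific birth counts (design-weighted counts may be
#' non-integer), the observed ratio `srb` and its log-scale sampling error
#' `log_se`.  `survey_year` is the year the survey was fielded (used for
#' recall filtering); it is `NA` for census observations.
#'
#' @param df data frame with columns `province`, `source`, `period_start`,
#'   `period_end`, `male_births`, `female_births`, `srb`, `log_se`,
#'   `survey_year`.
#' @param provinces optional character vector fixing the province ordering;
#'   defaults to order of first appearance.
#' @return `df` with class `srb_obs` and attribute `provinces`.
#' @export
as_srb_observations <- function(df, provinces = NULL) {
  missing_cols <- setdiff(srb_db_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("SRB database is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, srb_db_columns]
  df$province <- as.character(df$province)
  df$source <- as.character(df$source)
  if (nrow(df) > 0L) {
    bad <- function(cond, what) {
      if (any(cond, na.rm = TRUE)) {
        stop("invalid ", what, " in row(s) ",
             paste(which(cond), collapse = ", "), call. = FALSE)
      }
    }
    bad(df$male_births < 0, "male_births (must be >= 0)")
    bad(df$female_births <= 0, "female_births (must be > 0)")
    bad(df$period_start > df$period_end, "reference period (start > end)")
    bad(!(df$srb > 0), "srb (must be > 0)")
    bad(!(df$log_se > 0), "log_se (must be > 0)")
    ## when counts are present the ratio must be consistent with them
    have_counts <- !is.na(df$male_births) & !is.na(df$female_births)
    incons <- have_counts &
      abs(df$srb - df$male_births / df$female_births) > 1e-6 * df$srb
    bad(incons, "srb (inconsistent with male_births/female_births)")
  }
  if (is.null(provinces)) provinces <- unique(df$province)
  if (!all(df$province %in% provinces)) {
    stop("observation province(s) not in the province set: ",
         paste(setdiff(df$province, provinces), collapse = ", "),
         call. = FALSE)
  }
  structure(df, provinces = provinces,
            class = c("srb_obs", "data.frame"))
}

#' Load an SRB observation database from CSV
#'
#' Reads a comma-separated, UTF-8, one-header-row file with the documented
#' schema and returns a validated observation set.  Totals by source are
#' attached (attribute `source_totals`) so per-source observation counts and
#' birth totals are queryable without re-aggregation.
#'
#' @param path path to the CSV file.
#' @return an object of class `srb_obs` (see [as_srb_observations()]), with
#'   attributes `source_totals` (data frame: source, n_obs, births) and
#'   `total_births`.
#' @export
load_srb_database <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  obs <- as_srb_observations(raw)
  births <- obs$male_births + obs$female_births
  if (nrow(obs) > 0L) {
    tot <- stats::aggregate(
      cbind(n_obs = rep(1, nrow(obs)), births = births),
      by = list(source = obs$source), FUN = sum)
  } else {
    tot <- data.frame(source = character(), n_obs = numeric(),
                      births = numeric())
  }
  attr(obs, "source_totals") <- tot
  attr(obs, "total_births") <- sum(births)
  obs
}

#' Write an SRB observation database to CSV
#'
#' Inverse of [load_srb_database()]: writes the documented schema so that a
#' load/write round trip reproduces the file field-for-field.
#'
#' @param obs an `srb_obs` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_srb_database <- function(obs, path) {
  utils::write.csv(as.data.frame(obs)[, srb_db_columns], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Delta-method coefficient of variation of a ratio of counts
#'
#' For a ratio of independent counts m/f, the first-order (delta-method)
#' coefficient of variation is sqrt(1/m + 1/f); on the log scale this is
#' also the approximate standard error of log(m/f).
#'
#' @param male,female (weighted) birth counts, both > 0.
#' @return dimensionless CV.
#' @export
ratio_cv <- function(male, female) {
  stopifnot(all(male > 0), all(female > 0))
  sqrt(1 / male + 1 / female)
}

#' Merge one-year observation periods until sampling variability is controlled
#'
#' Survey full-birth-history data yield annual birth counts whose ratios are
#' too noisy to use directly.  Consecutive one-year observations from a
#' single province and source are pooled left-to-right into the shortest
#' periods whose pooled coefficient of variation (sqrt(1/m + 1/f), see
#' [ratio_cv()]) does not exceed `cv_max`.  Pooling sums male and female
#' births; the ratio and its log-scale error are recomputed from the pooled
#' counts, so total births are conserved exactly.
#'
#' A terminal remainder that cannot reach `cv_max` is emitted as-is with a
#' warning.
#'
#' @param annual_obs data frame of one-year observations (schema of
#'   [as_srb_observations()]) for a single province and source, sorted by
#'   `period_start`.
#' @param cv_max largest acceptable pooled CV; default 0.1 keeps log-scale
#'   sampling errors below about 0.1.
#' @return data frame of merged observations (same schema).
#' @export
merge_observation_periods <- function(annual_obs, cv_max = 0.1) {
  df <- as.data.frame(annual_obs)
  if (nrow(df) == 0L) return(df)
  if (length(unique(df$province)) != 1L || length(unique(df$source)) != 1L) {
    stop("merge_observation_periods() expects a single province and source",
         call. = FALSE)
  }
  if (is.unsorted(df$period_start)) {
    stop("annual observations must be sorted by period_start", call. = FALSE)
  }
  if (any(is.na(df$male_births)) || any(is.na(df$female_births))) {
    stop("period merging requires male/female birth counts", call. = FALSE)
  }
  out <- list()
  i <- 1L
  n <- nrow(df)
  while (i <= n) {
    m <- 0; f <- 0; j <- i
    repeat {
      m <- m + df$male_births[j]
      f <- f + df$female_births[j]
      ok <- m > 0 && f > 0 && ratio_cv(m, f) <= cv_max
      if (ok || j == n) break
      j <- j + 1L
    }
    if (!(m > 0 && f > 0 && ratio_cv(m, f) <= cv_max)) {
      warning("terminal period ", df$period_start[i], "-", df$period_end[j],
              " cannot reach cv_max = ", cv_max,
              "; emitted with its attained CV", call. = FALSE)
    }
    rec <- df[i, ]
    rec$period_end <- df$period_end[j]
    rec$male_births <- m
    rec$female_births <- f
    rec$srb <- m / f
    rec$log_se <- ratio_cv(m, f)
    out[[length(out) + 1L]] <- rec
    i <- j + 1L
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Jackknife standard error of the log sex ratio from clustered counts
#'
#' Delete-one-cluster jackknife for the log of a ratio estimator, the
#' standard way of reflecting multi-stage survey design in DHS-type data.
#' With k clusters, let theta_(i) be log(SRB) computed from all clusters but
#' i and theta_bar their mean; the variance estimate is
#' ((k - 1) / k) * sum_i (theta_(i) - theta_bar)^2.
#'
#' The estimator is invariant to uniform rescaling of all cluster weights
#' and to cluster order.
#'
#' @param clusters data frame with columns `male_births` and `female_births`
#'   (weighted counts, >= 0), one row per sampling cluster; at least 2 rows.
#' @return the jackknife standard error of log(SRB), a non-negative scalar.
#' @export
jackknife_log_se <- function(clusters) {
  cl <- as.data.frame(clusters)
  stopifnot(all(c("male_births", "female_births") %in% names(cl)))
  k <- nrow(cl)
  if (k < 2L) stop("jackknife requires at least 2 clusters", call. = FALSE)
  if (any(cl$male_births < 0) || any(cl$female_births < 0)) {
    stop("cluster birth counts must be non-negative", call. = FALSE)
  }
  tm <- sum(cl$male_births)
  tf <- sum(cl$female_births)
  m_i <- tm - cl$male_births
  f_i <- tf - cl$female_births
  degen <- which(m_i <= 0 | f_i <= 0)
  if (length(degen) > 0L) {
    stop("delete-one jackknife replicate degenerate (zero male or female ",
         "births) when excluding cluster(s) ",
         paste(degen, collapse = ", "), call. = FALSE)
  }
  theta <- log(m_i / f_i)
  sqrt((k - 1) / k * sum((theta - mean(theta))^2))
}

#' Drop survey observations beyond the recall window
#'
#' Full-birth-history surveys are retrospective; the sex composition of
#' births long before the interview suffers recall bias.  Survey
#' observations whose reference period starts more than `max_lag` years
#' before the survey year are dropped.  Census observations (missing
#' `survey_year`) pass through untouched.  The operation is idempotent.
#'
#' @param obs an `srb_obs` object or compatible data frame.
#' @param max_lag recall window in years (default 25); an observation with
#'   `period_start == survey_year - max_lag` is retained (boundary
#'   inclusive).
#' @return the filtered observation set, with attribute `n_dropped`.
#' @export
filter_recall_window <- function(obs, max_lag = 25) {
  df <- as.data.frame(obs)
  keep <- is.na(df$survey_year) |
    df$period_start >= df$survey_year - max_lag
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("filter_recall_window: dropped ", n_dropped,
            " observation(s) beyond the ", max_lag, "-year recall window")
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (inherits(obs, "srb_obs")) {
    out <- as_srb_observations(out, provinces = attr(obs, "provinces"))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Aggregate district-level census births to provincial SRB observations
#'
#' Census microdata samples cover districts unevenly; each district's birth
#' counts are inverse-probability weighted by its sampled fraction of the
#' population, then summed within province.  The provincial ratio is
#' recomputed from the weighted totals.  The log-scale error attached to
#' each provincial observation is the delta-method value
#' sqrt(1/M + 1/F) on the weighted totals.
#'
#' @param district_births data frame with columns `district`, `male_births`,
#'   `female_births`, `sampled_fraction` (in (0, 1]).
#' @param district_to_province named character vector mapping district to
#'   province.
#' @param year census reference year, used for both period bounds.
#' @param source label for the resulting observations (default "census").
#' @return data frame of provincial observations in the
#'   [as_srb_observations()] schema (`survey_year` is `NA`).
#' @export
aggregate_census_districts <- function(district_births, district_to_province,
                                       year, source = "census") {
  db <- as.data.frame(district_births)
  stopifnot(all(c("district", "male_births", "female_births",
                  "sampled_fraction") %in% names(db)))
  if (any(db$sampled_fraction <= 0 | db$sampled_fraction > 1)) {
    stop("sampled_fraction must lie in (0, 1]", call. = FALSE)
  }
  unmapped <- setdiff(db$district, names(district_to_province))
  if (length(unmapped) > 0L) {
    stop("district(s) not mapped to any province: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  w <- 1 / db$sampled_fraction
  prov <- district_to_province[db$district]
  m <- tapply(db$male_births * w, prov, sum)
  f <- tapply(db$female_births * w, prov, sum)
  out <- data.frame(
    province = names(m),
    source = source,
    period_start = year,
    period_end = year,
    male_births = as.numeric(m),
    female_births = as.numeric(f),
    srb = as.numeric(m / f),
    log_se = ratio_cv(as.numeric(m), as.numeric(f)),
    survey_year = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Reference year of an observation period
#'
#' Multi-year observation periods are evaluated at a single model year: the
#' midpoint (period_start + period_end) / 2, rounded down to an integer
#' calendar year.
#'
#' @param period_start,period_end inclusive calendar years.
#' @return integer reference year(s).
#' @export
period_midpoint_year <- function(period_start, period_end) {
  as.integer(floor((period_start + period_end) / 2))
}
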