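test_that("database loading validates the schema and reports totals", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tiny_obs_df()
  utils::write.csv(df, path, row.names = FALSE)
  obs <- load_srb_database(path)
  expect_s3_class(obs, "srb_obs")
  expect_equal(nrow(obs), 3L)
  expect_equal(attr(obs, "total_births"),
               sum(df$male_births + df$female_births))
  tot <- attr(obs, "source_totals")
  expect_setequal(tot$source, c("Survey 2011", "Census 2011"))
  expect_equal(tot$n_obs[tot$source == "Survey 2011"], 2)

  ## missing column is named in the error
  utils::write.csv(df[, setdiff(names(df), "log_se")], path,
                   row.names = FALSE)
  expect_error(load_srb_database(path), "log_se")

  ## non-positive sampling error names the row
  df_bad <- df; df_bad$log_se[2] <- 0
  utils::write.csv(df_bad, path, row.names = FALSE)
  expect_error(load_srb_database(path), "row\\(s\\) 2")

  ## empty file with a valid header loads as zero observations
  utils::write.csv(df[0, ], path, row.names = FALSE)
  expect_equal(nrow(load_srb_database(path)), 0L)
})

test_that("the srb field is the male/female ratio and is cross-checked", {
  df <- tiny_obs_df()[1:2, ]
  df$male_births <- c(105, 210)
  df$female_births <- c(100, 200)
  df$srb <- c(1.05, 1.05)
  obs <- as_srb_observations(df)
  expect_equal(obs$srb, c(1.05, 1.05))
  df$srb[1] <- 1.2  # inconsistent with the counts
  expect_error(as_srb_observations(df), "inconsistent")
})

test_that("write/load round trip reproduces the database field for field", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tiny_obs_df(), path, row.names = FALSE)
  obs <- load_srb_database(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_srb_database(obs, path2)
  obs2 <- load_srb_database(path2)
  expect_equal(as.data.frame(obs), as.data.frame(obs2))
})

test_that("period merging pools annual counts until the CV bound is met", {
  annual <- function(years, m, f) {
    data.frame(province = "Province 1", source = "Survey 2001",
               period_start = years, period_end = years,
               male_births = m, female_births = f, srb = m / f,
               log_se = sqrt(1 / m + 1 / f), survey_year = 2001,
               stringsAsFactors = FALSE)
  }
  ## single precise year: CV = sqrt(2/20000) = 0.01 <= 0.05, unchanged
  one <- annual(1990, 20000, 20000)
  expect_equal(merge_observation_periods(one, cv_max = 0.05), one)

  ## two noisy years pool into one record; CV = sqrt(2/1000)
  two <- annual(1990:1991, c(500, 500), c(500, 500))
  merged <- merge_observation_periods(two, cv_max = 0.05)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$period_start, 1990)
  expect_equal(merged$period_end, 1991)
  expect_equal(merged$male_births, 1000)
  expect_equal(merged$female_births, 1000)
  expect_equal(merged$log_se, sqrt(2 / 1000), tolerance = 1e-12)

  ## an infinite threshold never binds
  expect_equal(merge_observation_periods(two, cv_max = Inf), two)

  ## a terminal remainder that cannot meet the bound is emitted with a
  ## warning, and births are conserved in all cases
  three <- annual(1990:1992, c(4000, 4000, 30), c(4000, 4000, 30))
  expect_warning(m3 <- merge_observation_periods(three, cv_max = 0.05),
                 "terminal")
  expect_equal(sum(m3$male_births), sum(three$male_births))
  expect_equal(sum(m3$female_births), sum(three$female_births))

  ## contract errors
  expect_error(merge_observation_periods(annual(c(1991, 1990),
                                                c(10, 10), c(10, 10))),
               "sorted")
  mixed <- rbind(annual(1990, 10, 10),
                 within(annual(1991, 10, 10),
                        province <- "Province 2"))
  expect_error(merge_observation_periods(mixed), "single province")
})

test_that("period merging conserves births across random blocks", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    df <- data.frame(province = "Province 1", source = "S",
                     period_start = 1990 + seq_len(n) - 1,
                     period_end = 1990 + seq_len(n) - 1,
                     male_births = sample(20:4000, n),
                     female_births = sample(20:4000, n),
                     survey_year = 2016, stringsAsFactors = FALSE)
    df$srb <- df$male_births / df$female_births
    df$log_se <- sqrt(1 / df$male_births + 1 / df$female_births)
    merged <- suppressWarnings(merge_observation_periods(df, cv_max = 0.03))
    expect_equal(sum(merged$male_births), sum(df$male_births))
    expect_equal(sum(merged$female_births), sum(df$female_births))
    expect_true(all(merged$srb ==
                      merged$male_births / merged$female_births))
  }
})

test_that("jackknife log-SE matches the delete-one-cluster formula", {
  ## identical clusters: every replicate equals the full estimate
  same <- data.frame(male_births = rep(52, 10), female_births = rep(50, 10))
  expect_equal(jackknife_log_se(same), 0)

  ## two clusters, hand evaluation: replicates log(40/60) and log(60/40)
  two <- data.frame(male_births = c(60, 40), female_births = c(40, 60))
  expect_equal(jackknife_log_se(two), log(1.5), tolerance = 1e-12)

  ## scale invariance and order invariance
  set.seed(3)
  cl <- data.frame(male_births = rpois(8, 40) + 1,
                   female_births = rpois(8, 40) + 1)
  expect_equal(jackknife_log_se(cl),
               jackknife_log_se(cl * 3.7), tolerance = 1e-12)
  expect_equal(jackknife_log_se(cl),
               jackknife_log_se(cl[sample(8), ]), tolerance = 1e-12)

  ## contract errors
  expect_error(jackknife_log_se(cl[1, , drop = FALSE]), "at least 2")
  degen <- data.frame(male_births = c(10, 0), female_births = c(0, 10))
  expect_error(jackknife_log_se(degen), "cluster")
})

test_that("recall-window filtering is boundary-inclusive and idempotent", {
  df <- tiny_obs_df()
  df$period_start <- c(1986, 1985, 2011)  # lags 25, 26, census
  df$period_end <- df$period_start
  obs <- as_srb_observations(df)
  kept <- suppressMessages(filter_recall_window(obs, max_lag = 25))
  ## 26-year-old survey row dropped; 25-year-old retained; census untouched
  expect_equal(nrow(kept), 2L)
  expect_true(1986 %in% kept$period_start)
  expect_false(1985 %in% kept$period_start)
  expect_true(2011 %in% kept$period_start)
  expect_equal(attr(kept, "n_dropped"), 1L)
  ## idempotent
  again <- suppressMessages(filter_recall_window(kept, max_lag = 25))
  expect_equal(as.data.frame(again), as.data.frame(kept),
               ignore_attr = TRUE)
  ## max_lag = 0 keeps only the survey year itself
  df2 <- tiny_obs_df()
  df2$period_start <- c(2011, 2010, 2011)
  df2$period_end <- df2$period_start
  k0 <- suppressMessages(filter_recall_window(as_srb_observations(df2),
                                              max_lag = 0))
  expect_equal(nrow(k0), 2L)  # the 2011 survey row and the census row
})

test_that("census districts aggregate with inverse-probability weights", {
  map <- c(d1 = "Province 1", d2 = "Province 1", d3 = "Province 2")
  ## fully sampled districts just sum
  db <- data.frame(district = c("d1", "d2"),
                   male_births = c(50, 55), female_births = c(50, 50),
                   sampled_fraction = c(1, 1))
  out <- aggregate_census_districts(db, map, year = 2011)
  expect_equal(out$srb, 105 / 100)
  expect_equal(out$male_births, 105)
  ## a half-sampled district is doubled before summation
  db2 <- data.frame(district = "d1", male_births = 10, female_births = 10,
                    sampled_fraction = 0.5)
  out2 <- aggregate_census_districts(db2, map, year = 2011)
  expect_equal(out2$male_births, 20)
  expect_equal(out2$srb, 1)
  ## uneven coverage: weights 1/0.11 and 1/0.99
  db3 <- data.frame(district = c("d1", "d2"),
                    male_births = c(11, 99), female_births = c(11, 99),
                    sampled_fraction = c(0.11, 0.99))
  out3 <- aggregate_census_districts(db3, map, year = 2011)
  expect_equal(out3$male_births, 11 / 0.11 + 99 / 0.99)
  ## errors
  expect_error(aggregate_census_districts(
    within(db2, sampled_fraction <- 0), map, 2011), "sampled_fraction")
  expect_error(aggregate_census_districts(
    within(db2, district <- "dX"), map, 2011), "dX")
})

test_that("multi-year periods are referenced at their floored midpoint", {
  expect_equal(period_midpoint_year(2001, 2005), 2003L)
  expect_equal(period_midpoint_year(2000, 2001), 2000L)
  expect_equal(period_midpoint_year(2011, 2011), 2011L)
})
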