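test_that("conception date is an exact 14-day shift of the last menses", {
  expect_equal(derive_conception_date(as.Date("1994-10-24")),
               as.Date("1994-11-07"))
  expect_equal(derive_conception_date(as.Date("1999-12-20")),
               as.Date("2000-01-03"))   # year rollover
  expect_equal(derive_conception_date(as.Date("1996-02-16")),
               as.Date("1996-03-01"))   # leap-year February
  set.seed(11)
  d <- as.Date("1990-01-01") + sample.int(8000, 50)
  expect_true(all(derive_conception_date(d) - d == 14))
  expect_true(is.na(derive_conception_date(as.Date(NA))))
})

test_that("covariate coding follows the boundary and missing-parent rules", {
  r <- toy_records(6, "1994-06-01")
  r$mother_age <- c(36, 30, 28, 28, 34.5, 35)
  r$father_age <- c(34, NA, 28, 28, 35.5, NA)
  r$gestational_age <- c(36.9, 37, 40, NA, 40, 40)
  r$birth_weight <- c(2500, 2499, 3400, 3400, NA, 3400)
  r$mother_educ <- c(11, 12, 16, 16.5, 8, NA)
  r$father_educ <- c(11, 12, 16, 16.5, NA, NA)
  cov <- code_covariates(r)
  # mean parental age: boundary >= 35; mother-only when father missing
  expect_equal(cov$parental_age_35plus, c(1L, 0L, 0L, 0L, 1L, 1L))
  # strict-inequality outcome boundaries
  expect_equal(cov$preterm[1:3], c(1L, 0L, 0L))
  expect_true(is.na(cov$preterm[4]))
  expect_equal(cov$low_birth_weight[1:2], c(0L, 1L))
  expect_true(is.na(cov$low_birth_weight[5]))
  # education bins: <12, [12,16], >16, mother-only fallback
  expect_equal(as.character(cov$educ_category[1:5]),
               c("lt12", "12to16", "12to16", "gt16", "lt12"))
  expect_true(is.na(cov$educ_category[6]))
  expect_identical(levels(cov$educ_category), c("lt12", "12to16", "gt16"))
  expect_identical(levels(cov$race)[1], "non_hispanic_white")

  both_missing <- toy_records(1, "1994-06-01", mother_age = NA_real_,
                              father_age = NA_real_)
  expect_error(code_covariates(both_missing), "both parental ages")
  expect_error(code_covariates(toy_records(1, "1994-06-01", mother_age = 95)),
               "plausible")
  expect_error(code_covariates(toy_records(1, "1994-06-01",
                                           gestational_age = 60)),
               "plausible")
})

test_that("cohort filtering uses half-open dates and logs drops by reason", {
  r <- toy_records(10, as.Date("1994-06-01"))
  r$conception_date[1:2] <- as.Date("1992-01-15")       # before start
  r$conception_date[3] <- as.Date("1995-03-01")         # == end: excluded
  r$mother_age[4] <- NA; r$father_age[4] <- NA          # dropped
  r$conception_date[5] <- NA; r$last_menses[5] <- NA    # no date at all
  kept <- suppressMessages(filter_cohort(r, as.Date("1992-03-01"),
                                         as.Date("1995-03-01")))
  expect_equal(nrow(kept), 5L)
  log <- attr(kept, "drop_log")
  expect_equal(log$n[log$reason == "missing_or_invalid_conception_date"], 1L)
  expect_equal(log$n[log$reason == "missing_both_parental_ages"], 1L)
  expect_equal(log$n[log$reason == "outside_interval"], 3L)
  # start boundary is inclusive; conception date derived from last menses
  r2 <- toy_records(2, as.Date("1992-03-01"))
  r2$conception_date <- as.Date(NA)
  r2$last_menses <- as.Date("1992-03-01") - 14L
  kept2 <- suppressMessages(filter_cohort(r2, as.Date("1992-03-01"),
                                          as.Date("1995-03-01")))
  expect_equal(nrow(kept2), 2L)
  expect_equal(kept2$conception_date, rep(as.Date("1992-03-01"), 2))
  expect_warning(
    suppressMessages(filter_cohort(r2, as.Date("1999-01-01"),
                                   as.Date("1999-02-01"))),
    "no records remain")
})

test_that("daily aggregation zero-fills the section and conserves counts", {
  sec <- list(start = as.Date("1994-03-01"), end = as.Date("1997-03-01"))
  r <- toy_records(4, c("1994-11-07", "1994-11-07", "1994-11-07",
                        "1993-01-01"), is_case = c(1L, 0L, 0L, 1L))
  s <- build_daily_series(r, sec)
  i <- which(s$days == as.Date("1994-11-07"))
  expect_equal(s$totals[i], 3L)
  expect_equal(s$cases[i], 1L)
  expect_equal(s$N, 3L)  # out-of-section record not counted
  expect_equal(s$C, 1L)

  # a section spanning a leap day has 1096 zero bins when empty
  empty <- build_daily_series(toy_records(1, "1994-01-01")[0, ],
                              list(start = as.Date("1995-03-01"),
                                   end = as.Date("1998-03-01")))
  expect_equal(length(empty$days), 1096L)
  expect_true(all(empty$totals == 0L))
  expect_equal(empty$N, 0L)
  expect_equal(empty$C, 0L)

  # conservation on random cohorts
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200L
    r <- toy_records(n, as.Date("1994-03-01") + sample.int(1200, n, TRUE) - 1L,
                     is_case = rbinom(n, 1, 0.3))
    s <- build_daily_series(r, sec)
    insec <- r$conception_date >= sec$start & r$conception_date < sec$end
    expect_equal(s$N, sum(insec))
    expect_equal(s$C, sum(r$is_case == 1L & insec))
    expect_true(all(s$cases <= s$totals))
  }
  expect_error(daily_series(as.Date(c("1994-01-01", "1994-01-03")),
                            c(1L, 1L), c(0L, 0L)), "contiguous")
  expect_error(daily_series(as.Date("1994-01-01"), 1L, 2L), "exceed")
})

test_that("cohort summary percentages recompute exactly from its counts", {
  set.seed(21)
  n <- 400L
  r <- toy_records(n, as.Date("1993-01-01") + sample.int(700, n, TRUE) - 1L,
                   is_case = rbinom(n, 1, 0.05))
  r$medi_cal <- rbinom(n, 1, 0.43)
  r$sex_male <- 1L                      # all-male toy cohort
  r$gestational_age <- sample(c(35, 40), n, TRUE, prob = c(0.1, 0.9))
  r$mother_educ <- sample(c(10, 13, 17), n, TRUE)
  r$father_educ <- r$mother_educ
  r$race <- sample(c("non_hispanic_white", "hispanic_white", "black"),
                   n, TRUE)
  s <- summarize_cohort(r)
  expect_true(all(s$male_pct == 100L))
  expect_equal(sum(s$live_births), n)
  expect_equal(sum(s$cases), sum(r$is_case))
  # every percentage column equals the integer-rounded ratio of its count
  for (nm in grep("_pct$", names(s), value = TRUE)) {
    cnt <- s[[sub("_pct$", "_n", nm)]]
    expect_equal(s[[nm]], as.integer(round(100 * cnt / s$live_births)))
  }
  # education bins plus the lt12 reference close to the total
  cov <- code_covariates(r)
  yr <- as.integer(format(r$conception_date, "%Y"))
  for (k in seq_len(nrow(s))) {
    lt12 <- sum(cov$educ_category[yr == s$year[k]] == "lt12", na.rm = TRUE)
    expect_equal(s$educ_12to16_n[k] + s$educ_gt16_n[k] + lt12,
                 s$live_births[k])
  }
})
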